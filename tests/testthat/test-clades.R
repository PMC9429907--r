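# Phylogenetic clade calling: sporulation-clade membership with sigB
# exclusion, and maximal phage-only clades.

meta4 <- data.frame(tip = c("A", "B", "C", "D"),
                    source = c("phage", "phage", "bacterial", "bacterial"),
                    stringsAsFactors = FALSE)

test_that("annotated newick reading joins metadata and enforces coverage", {
  at <- read_annotated_newick("((A,B),(C,D));", meta4)
  expect_equal(ape::Ntip(at$tree), 4L)
  expect_equal(at$meta$tip, at$tree$tip.label)

  expect_error(read_annotated_newick("((A,B),(C,E));", meta4), "E")

  # unrooted trifurcation: needs a directive, outgroup rooting honoured
  expect_error(read_annotated_newick("(A,B,(C,D));", meta4), "unrooted")
  at2 <- read_annotated_newick("(A,B,(C,D));", meta4, root = "A")
  expect_true(ape::is.rooted(at2$tree))
  expect_true("A" %in% at2$tree$tip.label)
  at3 <- read_annotated_newick("(A:1,B:1,(C:1,D:1):1);", meta4,
                               root = "midpoint")
  expect_true(ape::is.rooted(at3$tree))
})

test_that("sporulation clade membership matches the hand-derived example", {
  nwk <- "(((sigF,(P1,sigG)),(sigB,P2)),outg);"
  meta <- data.frame(
    tip = c("sigF", "P1", "sigG", "sigB", "P2", "outg"),
    source = c("bacterial", "phage", "bacterial", "bacterial", "phage",
               "bacterial"),
    stringsAsFactors = FALSE)
  at <- read_annotated_newick(nwk, meta)
  cc <- suppressWarnings(
    sporulation_clade_members(at, c("sigF", "sigG"), "sigB"))
  expect_setequal(cc$clade_tips, c("sigF", "P1", "sigG"))
  expect_setequal(cc$excluded_subclade_tips, "sigB")
  expect_setequal(cc$member_phage_tips, "P1")

  # widen the spore references so the MRCA spans the sigB side too
  cc2 <- suppressWarnings(
    sporulation_clade_members(at, c("sigF", "sigG", "sigB"), "sigB"))
  expect_setequal(cc2$clade_tips, c("sigF", "P1", "sigG", "sigB", "P2"))
  expect_setequal(cc2$member_phage_tips, c("P1", "P2"))
})

test_that("degenerate membership cases: no phage tips, all phage in sigB", {
  meta <- data.frame(tip = c("F", "G", "B1", "B2", "X"),
                     source = c("bacterial", "bacterial", "bacterial",
                                "bacterial", "bacterial"))
  at <- read_annotated_newick("(((F,G),(B1,B2)),X);", meta)
  cc <- sporulation_clade_members(at, c("F", "B2"), c("B1", "B2"))
  expect_length(cc$member_phage_tips, 0)

  meta2 <- meta; meta2$source[5] <- "phage"; meta2$tip <- c("F","G","B1","B2","P")
  at2 <- read_annotated_newick("(((F,G),(B1,(B2,P))),outg);",
                               rbind(meta2, data.frame(tip = "outg",
                                                       source = "bacterial")))
  cc2 <- sporulation_clade_members(at2, c("F", "B2"), c("B1", "B2"))
  expect_length(cc2$member_phage_tips, 0)  # phage tip inside sigB subclade

  expect_error(sporulation_clade_members(at, "missing_tip", "B1"), "absent")
  expect_warning(sporulation_clade_members(at, c("F", "G"), c("B1", "B2")),
                 "not nested")
})

test_that("phage-only clades are maximal, disjoint, and cover phage tips", {
  at <- read_annotated_newick("((P1,P2),B1);",
                              data.frame(tip = c("P1", "P2", "B1"),
                                         source = c("phage", "phage",
                                                    "bacterial")))
  expect_equal(phage_only_clades(at), list(c("P1", "P2")))

  at2 <- read_annotated_newick("((P1,B1),(P2,B2));",
                               data.frame(tip = c("P1", "B1", "P2", "B2"),
                                          source = c("phage", "bacterial",
                                                     "phage", "bacterial")))
  expect_setequal(lapply(phage_only_clades(at2), sort), list("P1", "P2"))

  allp <- read_annotated_newick("((P1,P2),(P3,P4));",
                                data.frame(tip = paste0("P", 1:4),
                                           source = "phage"))
  expect_setequal(phage_only_clades(allp)[[1]], paste0("P", 1:4))

  nob <- read_annotated_newick("((B1,B2),B3);",
                               data.frame(tip = paste0("B", 1:3),
                                          source = "bacterial"))
  expect_equal(phage_only_clades(nob), list())
})

test_that("clade calls agree with brute-force enumeration on random trees", {
  set.seed(42)
  for (i in 1:40) {
    rt <- oracle_random_annotated_tree(sample(8:40, 1))
    at <- list(tree = rt$tree, meta = rt$meta)
    class(at) <- "annotated_tree"
    bact <- rt$meta$tip[rt$meta$source == "bacterial"]
    spore_refs <- sample(bact, sample(2:3, 1))
    sigb_refs <- sample(bact, 2)
    got <- suppressWarnings(
      sporulation_clade_members(at, spore_refs, sigb_refs))
    exp <- oracle_clade_members(rt$tree, rt$meta, spore_refs, sigb_refs)
    expect_equal(sort(got$clade_tips), exp$clade)
    expect_equal(sort(got$excluded_subclade_tips), exp$excl)
    expect_equal(sort(got$member_phage_tips), exp$members)

    got_po <- lapply(phage_only_clades(at), sort)
    exp_po <- oracle_phage_only(rt$tree, rt$meta)
    expect_setequal(got_po, exp_po)

    # partition property over phage tips
    phage <- rt$meta$tip[rt$meta$source == "phage"]
    expect_setequal(as.character(unlist(got_po)), phage)
    expect_equal(anyDuplicated(unlist(got_po)), 0L)
  }
})

test_that("calls are invariant to child-order rotation of the topology", {
  g <- gen_tree(4, 3, n_phage_in_sigb = 1, seed = 13)
  at <- read_annotated_newick(g$newick, g$metadata)
  base <- sporulation_clade_members(at, c("Bs_sigF", "Bs_sigE"),
                                    c("Bs_sigB", "Bc_sigB"))
  base_po <- lapply(phage_only_clades(at), sort)
  rot <- at
  ntip <- ape::Ntip(rot$tree)
  for (nd in (ntip + 1):(ntip + rot$tree$Nnode))
    rot$tree <- ape::rotate(rot$tree, nd)
  rotated <- sporulation_clade_members(rot, c("Bs_sigF", "Bs_sigE"),
                                       c("Bs_sigB", "Bc_sigB"))
  expect_setequal(rotated$member_phage_tips, base$member_phage_tips)
  expect_setequal(lapply(phage_only_clades(rot), sort), base_po)
})
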