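# Homology-based classification of sigma-factor proteins.
#
# Proteins are assigned to the sigma-factor family of their best (smallest
# sequence E-value) HMM hit. Two umbrella families ("sigma70-ECF", "SigBFG")
# match almost any sigma factor; when the best hit is one of these and a more
# specific hit exists, the next best non-general family is used instead.

#' Build a sigma-factor family catalog
#'
#' The catalog declares which family identifiers are "general" umbrella
#' families (fallback applies when they win the best hit) and which are
#' sporulation-specific.
#'
#' @param family_id Character vector of unique family identifiers.
#' @param is_general Logical vector; TRUE for umbrella families.
#' @param is_spore_like Logical vector; TRUE for sporulation-specific families.
#' @return A `family_catalog` data frame.
#' @export
family_catalog <- function(family_id, is_general, is_spore_like) {
  family_id <- as.character(family_id)
  if (anyDuplicated(family_id)) stop("family_catalog: duplicate family_id")
  if (length(is_general) != length(family_id) ||
      length(is_spore_like) != length(family_id))
    stop("family_catalog: field lengths differ")
  if (any(is_general & is_spore_like))
    stop("family_catalog: a general family cannot be spore-like")
  out <- data.frame(family_id = family_id,
                    is_general = as.logical(is_general),
                    is_spore_like = as.logical(is_spore_like),
                    stringsAsFactors = FALSE)
  class(out) <- c("family_catalog", "data.frame")
  out
}

#' Default sigma-factor family catalog
#'
#' Ships the forespore/mother-cell sporulation cascade families (sigF, sigE,
#' sigG, sigK style), the two umbrella families, and common non-sporulation
#' families. Real analyses map their own profile accessions onto this schema.
#'
#' @return A `family_catalog`.
#' @export
default_family_catalog <- function() {
  fams <- c("spore_sigF", "spore_sigE", "spore_sigG", "spore_sigK",
            "sigma70-ECF", "SigBFG",
            "sigma70_primary", "sigma54", "flagellar_sigD", "heatshock_sigH")
  family_catalog(fams,
                 is_general = fams %in% c("sigma70-ECF", "SigBFG"),
                 is_spore_like = fams %in% c("spore_sigF", "spore_sigE",
                                             "spore_sigG", "spore_sigK"))
}

#' Parse a tblout-style homology hit table
#'
#' Reads the whitespace-delimited tabular output dialect of profile HMM
#' searches: `#`-prefixed comment lines, then one row per (target family,
#' query protein) domain hit. Only the target name (column 1), query name
#' (column 3), full-sequence E-value (column 5) and score (column 6) are used.
#' Multiple domain rows for the same (protein, family) pair are collapsed to
#' the smallest sequence E-value.
#'
#' @param path Path to the hit table (or a connection).
#' @return Data frame with columns `protein_id`, `family_id`, `evalue`,
#'   `score`, one row per (protein, family).
#' @export
parse_hmm_tblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(protein_id = character(), family_id = character(),
                      evalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 6))
    stop("parse_hmm_tblout: line ", which(nf < 6)[1], " has fewer than 6 fields")
  fam <- vapply(fields, `[[`, "", 1L)
  prot <- vapply(fields, `[[`, "", 3L)
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  if (anyNA(ev))
    stop("parse_hmm_tblout: malformed E-value on line ", which(is.na(ev))[1])
  if (anyNA(sc))
    stop("parse_hmm_tblout: malformed score on line ", which(is.na(sc))[1])
  if (any(ev <= 0))
    stop("parse_hmm_tblout: non-positive E-value on line ", which(ev <= 0)[1])
  tab <- data.frame(protein_id = prot, family_id = fam, evalue = ev,
                    score = sc, stringsAsFactors = FALSE)
  # collapse per (protein, family) to best sequence-level E-value, keeping
  # first-appearance order of the pairs
  key <- paste(tab$protein_id, tab$family_id, sep = "\r")
  best <- tapply(seq_len(nrow(tab)), key, function(i) {
    i[order(tab$evalue[i], -tab$score[i])][1]
  })
  keep <- sort(unname(best))
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Classify one protein from its homology hits
#'
#' Assigns the family of the smallest sequence E-value. If that family is a
#' general umbrella family and a non-general hit exists, the best non-general
#' hit is used instead and `fallback_used` is set. Proteins whose only hits
#' are general keep the general assignment and are not spore-like. Ties on
#' E-value are broken by higher bit score, then lexicographic family id.
#'
#' @param hits Data frame with columns `family_id`, `evalue`, optional `score`,
#'   all hits belonging to a single protein. May have zero rows.
#' @param catalog A [family_catalog()].
#' @return List with `assigned_family` (or `NA`), `spore_like`,
#'   `fallback_used`, `evalue` of the assigned hit (or `NA`).
#' @export
classify_protein <- function(hits, catalog) {
  stopifnot(inherits(catalog, "family_catalog"))
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(assigned_family = NA_character_, spore_like = FALSE,
                fallback_used = FALSE, evalue = NA_real_))
  }
  unknown <- setdiff(hits$family_id, catalog$family_id)
  if (length(unknown))
    stop("classify_protein: unknown family id(s): ",
         paste(unknown, collapse = ", "))
  if (any(hits$evalue <= 0)) stop("classify_protein: E-values must be > 0")
  score <- if ("score" %in% names(hits)) hits$score else rep(0, nrow(hits))
  ord <- order(hits$evalue, -score, hits$family_id)
  ranked <- hits$family_id[ord]
  general <- catalog$is_general[match(ranked, catalog$family_id)]
  pick <- 1L
  fallback <- FALSE
  if (general[1] && any(!general)) {
    pick <- which(!general)[1]
    fallback <- TRUE
  }
  fam <- ranked[pick]
  list(assigned_family = fam,
       spore_like = catalog$is_spore_like[match(fam, catalog$family_id)],
       fallback_used = fallback,
       evalue = hits$evalue[ord][pick])
}

#' Classify every protein in a hit table
#'
#' @param hit_table Output of [parse_hmm_tblout()] (or the same schema).
#' @param catalog A [family_catalog()].
#' @param protein_ids Optional character vector of proteins to report even if
#'   they have no hits (assigned `NA`).
#' @return Data frame with one row per protein: `protein_id`,
#'   `assigned_family`, `spore_like`, `fallback_used`, `evalue`.
#' @export
classify_proteins <- function(hit_table, catalog, protein_ids = NULL) {
  ids <- unique(c(hit_table$protein_id, protein_ids))
  rows <- lapply(ids, function(p) {
    res <- classify_protein(hit_table[hit_table$protein_id == p, , drop = FALSE],
                            catalog)
    data.frame(protein_id = p, assigned_family = res$assigned_family,
               spore_like = res$spore_like, fallback_used = res$fallback_used,
               evalue = res$evalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize sigma-factor content per genome and per host phylum
#'
#' A genome is flagged spore-like when at least one of its proteins is
#' classified into a sporulation-specific family (a genome carrying both
#' spore-like and non-spore-like sigma factors counts as spore-like). The
#' genome-level distribution bins genomes by sigma-factor count (0/1/2/3+).
#' Host phyla with fewer genomes than `min_genomes_per_phylum` are flagged
#' `below_display_threshold` but kept in the table.
#'
#' @param assignments Data frame from [classify_proteins()] plus a
#'   `genome_id` column mapping each protein to its genome.
#' @param genome_catalog Data frame with `genome_id` and `host_phylum`
#'   (NA allowed) covering every genome, including genomes with no sigma hits.
#' @param min_genomes_per_phylum Display threshold (default 10).
#' @return List with `genomes` (per-genome summary), `count_distribution`
#'   (fractions over the 0/1/2/3+ bins) and `phylum_table` (per-phylum genome
#'   and spore-like counts).
#' @export
summarize_genomes <- function(assignments, genome_catalog,
                              min_genomes_per_phylum = 10L) {
  if (!all(c("genome_id", "host_phylum") %in% names(genome_catalog)))
    stop("summarize_genomes: genome_catalog needs genome_id and host_phylum")
  if (nrow(assignments) > 0) {
    if (!"genome_id" %in% names(assignments))
      stop("summarize_genomes: assignments need a genome_id column")
    missing <- setdiff(assignments$genome_id, genome_catalog$genome_id)
    if (length(missing))
      stop("summarize_genomes: genome id(s) missing from catalog: ",
           paste(missing, collapse = ", "))
  }
  gid <- genome_catalog$genome_id
  n_sigma <- integer(length(gid))
  spore <- logical(length(gid))
  if (nrow(assignments) > 0) {
    assigned <- assignments[!is.na(assignments$assigned_family), , drop = FALSE]
    if (nrow(assigned) > 0) {
      cnt <- table(assigned$genome_id)
      n_sigma[match(names(cnt), gid)] <- as.integer(cnt)
      sl <- tapply(assigned$spore_like, assigned$genome_id, any)
      spore[match(names(sl), gid)] <- as.logical(sl)
    }
  }
  genomes <- data.frame(genome_id = gid,
                        host_phylum = genome_catalog$host_phylum,
                        n_sigma = n_sigma, spore_like_flag = spore,
                        stringsAsFactors = FALSE)
  bins <- cut(genomes$n_sigma, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
              labels = c("0", "1", "2", "3+"))
  frac <- as.numeric(table(bins)) / nrow(genomes)
  count_distribution <- data.frame(n_sigma = c("0", "1", "2", "3+"),
                                   n_genomes = as.integer(table(bins)),
                                   fraction = frac, stringsAsFactors = FALSE)
  phy <- ifelse(is.na(genomes$host_phylum), "unknown", genomes$host_phylum)
  phylum_table <- do.call(rbind, lapply(unique(phy), function(p) {
    sub <- genomes[phy == p, , drop = FALSE]
    data.frame(host_phylum = p, n_genomes = nrow(sub),
               n_spore_like = sum(sub$spore_like_flag),
               n_with_sigma = sum(sub$n_sigma > 0),
               below_display_threshold = nrow(sub) < min_genomes_per_phylum,
               stringsAsFactors = FALSE)
  }))
  rownames(phylum_table) <- NULL
  list(genomes = genomes, count_distribution = count_distribution,
       phylum_table = phylum_table)
}

#' Agreement between two classification methods
#'
#' Compares the protein sets called sporulation-like by the phylogenetic and
#' the homology route.
#'
#' @param set_phylo,set_hmm Character vectors of protein ids.
#' @return List with `n_phylo`, `n_hmm`, `n_both`, `jaccard`.
#' @export
method_agreement <- function(set_phylo, set_hmm) {
  a <- unique(as.character(set_phylo)); b <- unique(as.character(set_hmm))
  both <- length(intersect(a, b)); un <- length(union(a, b))
  list(n_phylo = length(a), n_hmm = length(b), n_both = both,
       jaccard = if (un == 0) NA_real_ else both / un)
}
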