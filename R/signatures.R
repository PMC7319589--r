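# Graph-based (cutoff scanning matrix) signatures: cumulative counts of
# pharmacophore class pairs over increasing distance thresholds in the
# environment of the mutated sites, plus per-class pharmacophore change
# vectors between wild-type and mutant residues.

PHARM_CLASSES <- c("hydrophobic", "positive", "negative", "acceptor",
                   "donor", "aromatic", "sulfur", "neutral")

the <- new.env(parent = emptyenv())  # package-local caches

#' Pharmacophore atom-class table
#'
#' The eight-class assignment (hydrophobic, positive, negative, hydrogen-bond
#' acceptor, hydrogen-bond donor, aromatic, sulfur, neutral) for every heavy
#' atom of the 20 standard residues, read from the versioned data file
#' shipped with the package. An atom may carry several classes.
#'
#' @param path Path to a class TSV (`resname`, `atom`, comma-separated
#'   `class`); defaults to the shipped table.
#' @return A tibble with columns `resname`, `atom`, `class` (one row per
#'   atom, classes comma-separated).
#' @export
pharmacophore_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$pharm_table)) return(the$pharm_table)
    path <- system.file("extdata", "pharmacophores.tsv", package = "abddg")
    tab <- readr::read_tsv(path, comment = "#", col_names = c("resname", "atom", "class"),
                           col_types = "ccc", progress = FALSE)
    the$pharm_table <- tab
    return(tab)
  }
  readr::read_tsv(path, comment = "#", col_names = c("resname", "atom", "class"),
                  col_types = "ccc", progress = FALSE)
}

#' Pharmacophore classes of one atom
#'
#' @param resname Three-letter residue name.
#' @param atom PDB atom name.
#' @param table A [pharmacophore_table()].
#' @return Character vector of classes; empty (with a warning) for an atom
#'   absent from the table.
#' @export
atom_classes <- function(resname, atom, table = pharmacophore_table()) {
  hit <- table$class[table$resname == toupper(resname) & table$atom == toupper(atom)]
  if (length(hit) == 0) {
    warning("unknown atom for pharmacophore typing: ", resname, " ", atom)
    return(character())
  }
  strsplit(hit[1], ",", fixed = TRUE)[[1]]
}

# 0/1 class-membership matrix (n_atoms x 8) for rows of an atom table;
# atoms missing from the class table get all-zero rows (with one warning).
class_matrix <- function(resname, atom, table = pharmacophore_table()) {
  key <- paste(table$resname, table$atom)
  idx <- match(paste(toupper(resname), toupper(atom)), key)
  if (anyNA(idx))
    warning("unknown atoms for pharmacophore typing: ",
            paste(unique(paste(resname, atom)[is.na(idx)]), collapse = ", "))
  m <- matrix(0L, length(idx), length(PHARM_CLASSES),
              dimnames = list(NULL, PHARM_CLASSES))
  cls <- strsplit(ifelse(is.na(idx), "", table$class[idx]), ",", fixed = TRUE)
  for (i in seq_along(cls)) m[i, cls[[i]]] <- 1L
  m
}

#' Signature distance-bin parameters
#'
#' @param d_min,d_max,step Bin geometry in Angstrom; `(d_max - d_min) / step`
#'   must be integral. Default bins have upper edges 2.5, 4.0, ..., 10.0.
#' @param environment_radius Heavy atoms within this radius of any atom of a
#'   mutated site define the signature environment (Angstrom).
#' @return A list of class `signature_params`.
#' @export
signature_params <- function(d_min = 1, d_max = 10, step = 1.5,
                             environment_radius = 10) {
  stopifnot(d_min > 0, d_max > d_min, step > 0)
  n_bins <- (d_max - d_min) / step
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("(d_max - d_min) / step must be integral")
  structure(list(d_min = d_min, d_max = d_max, step = step,
                 environment_radius = environment_radius,
                 edges = d_min + step * seq_len(round(n_bins))),
            class = "signature_params")
}

unordered_class_pairs <- function() {
  idx <- which(upper.tri(diag(length(PHARM_CLASSES)), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(a = PHARM_CLASSES[idx[, "row"]], b = PHARM_CLASSES[idx[, "col"]])
}

#' Cutoff scanning matrix signature of a residue environment
#'
#' The environment is the set of heavy atoms within `environment_radius` of
#' any heavy atom of any mutated site. For every unordered pair of
#' environment atoms with separation in `[d_min, d_max]`, the pair is
#' counted cumulatively (separation <= edge) in every unordered class-pair
#' cell induced by the two atoms' class sets.
#'
#' @param complex An [as_complex()] object.
#' @param sites Character vector of residue keys (the mutated sites).
#' @param params A [signature_params()].
#' @param table A [pharmacophore_table()].
#' @return A tibble (`class_a`, `class_b`, `edge`, `count`) of cumulative
#'   counts, 36 class pairs x length(edges) rows, with `params` attached as
#'   an attribute.
#' @export
csm_signature <- function(complex, sites, params = signature_params(),
                          table = pharmacophore_table()) {
  miss <- setdiff(sites, complex$key)
  if (length(miss) > 0) stop("unknown sites: ", paste(miss, collapse = ", "))
  xyz <- coords_matrix(complex)
  site_xyz <- xyz[complex$key %in% sites, , drop = FALSE]
  near <- apply(cross_dist(xyz, site_xyz), 1, min) <= params$environment_radius
  if (sum(near) == 0) stop("empty signature environment: degenerate structure")
  env_xyz <- xyz[near, , drop = FALSE]
  cm <- class_matrix(complex$resname[near], complex$atom[near], table)
  d <- cross_dist(env_xyz, env_xyz)
  ut <- upper.tri(d)
  sel <- ut & d >= params$d_min & d <= params$d_max
  pi_ <- row(d)[sel]; pj <- col(d)[sel]; pd <- d[sel]
  pairs <- unordered_class_pairs()
  n_e <- length(params$edges)
  counts <- matrix(0L, nrow(pairs), n_e)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$a[k]; b <- pairs$b[k]
    hit <- (cm[pi_, a] & cm[pj, b]) | (cm[pi_, b] & cm[pj, a])
    dd <- pd[hit]
    counts[k, ] <- vapply(params$edges, function(e) sum(dd <= e), 0L)
  }
  out <- tibble::tibble(
    class_a = rep(pairs$a, each = n_e), class_b = rep(pairs$b, each = n_e),
    edge = rep(params$edges, nrow(pairs)), count = as.integer(t(counts))
  )
  attr(out, "params") <- params
  out
}

#' Flatten a signature into a named feature vector
#'
#' Feature names are stable and part of the model contract:
#' `sig.<class_a>:<class_b>.<edge>`.
#'
#' @param sig A [csm_signature()] tibble.
#' @return Named numeric vector.
#' @export
signature_vector <- function(sig) {
  stats::setNames(as.numeric(sig$count),
                  sprintf("sig.%s:%s.%g", sig$class_a, sig$class_b, sig$edge))
}

#' Pharmacophore change upon mutation
#'
#' Per-class signed difference between the heavy-atom class counts of the
#' idealized mutant and wild-type residues (side chain + backbone).
#'
#' @param wt_aa,mt_aa One-letter codes.
#' @param table A [pharmacophore_table()].
#' @return Named integer vector over the eight classes (mutant minus
#'   wild-type), names `pc.<class>`.
#' @export
pharmacophore_change <- function(wt_aa, mt_aa, table = pharmacophore_table()) {
  counts <- function(code1) {
    tmpl <- residue_template(aa_three(code1))
    colSums(class_matrix(rep(aa_three(code1), nrow(tmpl)), tmpl$atom, table))
  }
  delta <- counts(mt_aa) - counts(wt_aa)
  stats::setNames(as.integer(delta), paste0("pc.", PHARM_CLASSES))
}
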