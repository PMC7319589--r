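# Evolutionary features: PAM30 substitution scores (NCBI matrix text shipped
# in-repo) and per-position PSSM scores consumed from PSI-BLAST ASCII output.
# PSSMs are inputs, never computed here; when absent, PAM30-only features
# with dataset-median imputation keep the pipeline offline-complete.

PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read an NCBI-format substitution matrix
#'
#' @param path Matrix text file (`#` comments, a column-letter header, one
#'   row per letter). Defaults to the PAM30 file shipped with the package.
#' @return An integer matrix with row/column names; the 20 standard letters
#'   are guaranteed present.
#' @export
read_pam30 <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$pam30)) return(the$pam30)
    path <- system.file("extdata", "PAM30.txt", package = "abddg")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- matrix(NA_integer_, length(rows), length(header),
              dimnames = list(vapply(rows, `[`, "", 1), header))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1]
    if (length(vals) != length(header))
      stop("ragged matrix row for letter ", rows[[i]][1])
    m[i, ] <- as.integer(vals)
  }
  if (!all(PSSM_ALPHABET %in% rownames(m)))
    stop("matrix lacks standard amino-acid letters")
  the$pam30 <- m
  m
}

#' PAM30 substitution score
#'
#' @param wt_aa,mt_aa One-letter codes (vectorized).
#' @param matrix A substitution matrix from [read_pam30()].
#' @return Integer score(s); symmetric in its arguments.
#' @export
pam30_score <- function(wt_aa, mt_aa, matrix = read_pam30()) {
  wt_aa <- toupper(wt_aa); mt_aa <- toupper(mt_aa)
  bad <- !(wt_aa %in% PSSM_ALPHABET) | !(mt_aa %in% PSSM_ALPHABET)
  if (any(bad)) stop("nonstandard amino-acid code: ",
                     paste(unique(c(wt_aa, mt_aa)[c(bad, bad)]), collapse = ", "))
  matrix[cbind(wt_aa, mt_aa)]
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: a header, then one row per position
#' with the position index, the query residue letter and 20 log-odds
#' integers (any trailing percentage/information columns are ignored).
#'
#' @param path PSSM text file.
#' @return A `pssm_profile`: tibble with `position`, `letter` and the 20
#'   log-odds columns named by residue letter.
#' @export
read_ascii_pssm <- function(path) {
  lines <- readLines(path)
  # locate the header row carrying the 20 (or 40) column letters
  hdr <- which(vapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    length(f) >= 20 && all(PSSM_ALPHABET %in% f)
  }, TRUE))[1]
  if (is.na(hdr)) stop("malformed PSSM header in ", path)
  cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]][seq_along(PSSM_ALPHABET)]
  body <- lines[-seq_len(hdr)]
  body <- body[grepl("^\\s*[0-9]+\\s+[A-Z]", body)]
  if (length(body) == 0) stop("no PSSM rows in ", path)
  rows <- strsplit(trimws(body), "\\s+")
  out <- matrix(NA_integer_, length(rows), 20, dimnames = list(NULL, cols))
  pos <- integer(length(rows)); letter <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 22)
      stop("ragged PSSM row at line ", hdr + which(grepl("^\\s*[0-9]+\\s+[A-Z]", lines[-seq_len(hdr)]))[i],
           " (", length(f) - 2, " score columns)")
    pos[i] <- as.integer(f[1]); letter[i] <- f[2]
    out[i, ] <- as.integer(f[3:22])
  }
  prof <- tibble::as_tibble(out)
  prof <- dplyr::bind_cols(tibble::tibble(position = pos, letter = letter), prof)
  class(prof) <- c("pssm_profile", class(prof))
  prof
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Used by the fixture generator; [read_ascii_pssm()] round-trips its output.
#'
#' @param profile A `pssm_profile` tibble.
#' @param path Output path.
#' @export
write_ascii_pssm <- function(profile, path) {
  lines <- c("", "Last position-specific scoring matrix computed",
             paste0("            ", paste(sprintf("%3s", PSSM_ALPHABET), collapse = " ")))
  for (i in seq_len(nrow(profile))) {
    sc <- as.integer(profile[i, PSSM_ALPHABET])
    lines <- c(lines, paste0(sprintf("%5d %s  ", profile$position[i], profile$letter[i]),
                             paste(sprintf("%3d", sc), collapse = " "),
                             "   0.00 0.00"))
  }
  writeLines(lines, path)
  invisible(path)
}

# Map a chain's structure residues onto profile positions by exact sequence
# match; any mismatch or length difference is an error (never silent shift).
map_profile_to_chain <- function(profile, complex, chain) {
  res <- complex_residues(complex)
  res <- res[res$chain == chain, , drop = FALSE]
  if (nrow(res) == 0) stop("chain not in structure: ", chain)
  if (nrow(res) != nrow(profile))
    stop("PSSM length (", nrow(profile), ") does not match chain ", chain,
         " length (", nrow(res), ")")
  seq_struct <- aa_one(res$resname)
  if (!all(seq_struct == profile$letter))
    stop("PSSM sequence mismatch on chain ", chain, " at position ",
         which(seq_struct != profile$letter)[1])
  stats::setNames(seq_len(nrow(res)), res$key)
}

#' PSSM-derived features for one point mutation
#'
#' @param profile A `pssm_profile` for the mutated chain (or `NULL` for the
#'   missing-PSSM fallback).
#' @param spec One row of a mutation spec tibble.
#' @param complex The complex (for sequence mapping).
#' @return A one-row tibble `wt_score`, `mt_score`, `delta` (wt - mt),
#'   `missing`. When `profile` is `NULL` the scores are `NA` and `missing`
#'   is 1; imputation happens at the dataset level.
#' @export
pssm_features <- function(profile, spec, complex) {
  if (is.null(profile))
    return(tibble::tibble(wt_score = NA_real_, mt_score = NA_real_,
                          delta = NA_real_, missing = 1))
  key <- res_key(spec$chain, spec$resno, spec$icode)
  mapping <- map_profile_to_chain(profile, complex, spec$chain)
  if (!key %in% names(mapping)) stop("unmappable mutation position: ", key)
  row <- profile[mapping[[key]], ]
  if (row$letter != spec$wt)
    stop("PSSM letter ", row$letter, " does not match wild-type ", spec$wt,
         " at ", key)
  wt <- as.numeric(row[[spec$wt]]); mt <- as.numeric(row[[spec$mt]])
  tibble::tibble(wt_score = wt, mt_score = mt, delta = wt - mt, missing = 0)
}
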