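# Affinity-record curation: thermodynamic conversions, reverse-mutation
# augmentation, additive/synergistic labelling, non-binder handling and a
# documented CSV schema.

# gas constant, kcal mol^-1 K^-1
R_KCAL <- 1.987e-3

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(K_D)` with R = 1.987e-3 kcal/(mol K).
#'
#' @param kd Dissociation constant, molar (> 0). Vectorized.
#' @param temperature Kelvin (> 0).
#' @return kcal/mol.
#' @export
delta_g_from_kd <- function(kd, temperature = 298) {
  if (any(!is.na(kd) & kd <= 0)) stop("K_D must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  R_KCAL * temperature * log(kd)
}

#' Change in binding free energy of a record
#'
#' `ddG = dG_wild - dG_mutant`; positive means the mutant binds tighter.
#' Records carrying a direct `ddg` return it; otherwise it is derived from
#' the K_D pair at the record's temperature.
#'
#' @param records Affinity-record tibble (columns `kd_wt`, `kd_mut`,
#'   `temperature`, optionally `ddg`, `is_non_binder`).
#' @return Numeric vector, kcal/mol.
#' @export
ddg_of <- function(records) {
  if ("is_non_binder" %in% names(records) &&
      any(records$is_non_binder %in% TRUE))
    stop("ddG is undefined for non-binder records")
  direct <- if ("ddg" %in% names(records)) records$ddg else rep(NA_real_, nrow(records))
  derived <- rep(NA_real_, nrow(records))
  has_kd <- !is.na(records$kd_wt) & !is.na(records$kd_mut)
  tk <- if ("temperature" %in% names(records)) records$temperature else rep(298, nrow(records))
  tk[is.na(tk)] <- 298
  derived[has_kd] <- delta_g_from_kd(records$kd_wt[has_kd], tk[has_kd]) -
    delta_g_from_kd(records$kd_mut[has_kd], tk[has_kd])
  out <- ifelse(is.na(direct), derived, direct)
  if (any(is.na(out))) stop("record without K_D pair or direct ddG")
  out
}

#' Augment a training set with hypothetical reverse mutations
#'
#' For every eligible single-point forward record (|ddG| below
#' `threshold_kcal`), emits a reverse record: the modelled mutant structure
#' becomes the wild-type context, the mutation letters are swapped, the ddG
#' is negated and `is_reverse` is set. Originals are retained.
#'
#' @param train Tibble of single-point, non-reverse affinity records with a
#'   `mutations` column in the `CHAIN.WT<number><icode?>MT` dialect.
#' @param threshold_kcal Eligibility bound on |ddG| (strict; default 2).
#' @return The input records followed by the reverse records.
#' @export
augment_reverse <- function(train, threshold_kcal = 2) {
  if (any(grepl(";", train$mutations, fixed = TRUE)))
    stop("augmentation applies to single-point records only")
  if ("is_reverse" %in% names(train) && any(train$is_reverse %in% TRUE))
    stop("input records must not be reverse records")
  ddg <- ddg_of(train)
  train$ddg <- ddg
  eligible <- abs(ddg) < threshold_kcal
  rev <- train[eligible, , drop = FALSE]
  if (nrow(rev) > 0) {
    sp <- parse_mutation_list(paste(rev$mutations, collapse = "\n"))
    rev$mutations <- paste0(sp$chain, ".", sp$mt, sp$resno, sp$icode, sp$wt)
    rev$ddg <- -rev$ddg
    tmp <- rev$kd_wt; rev$kd_wt <- rev$kd_mut; rev$kd_mut <- tmp
    rev$is_reverse <- TRUE
    rev$forward_id <- which(eligible)
  }
  train$forward_id <- seq_len(nrow(train))
  dplyr::bind_rows(train, rev)
}

#' Label a multi-point record as additive or synergistic
#'
#' Additive iff the sum of the constituent single-point ddGs lies within
#' `tol_kcal` of the multi-point ddG; `unlabelable` when any constituent
#' single-point measurement is missing.
#'
#' @param multi One multi-point affinity record (one-row tibble).
#' @param singles Tibble of single-point records of the same complex.
#' @param tol_kcal Tolerance, kcal/mol (default 1).
#' @return `"additive"`, `"synergistic"` or `"unlabelable"`.
#' @export
label_additivity <- function(multi, singles, tol_kcal = 1) {
  stopifnot(nrow(multi) == 1)
  parts <- trimws(strsplit(multi$mutations, ";", fixed = TRUE)[[1]])
  sel <- singles$complex_id == multi$complex_id & singles$mutations %in% parts
  found <- singles[sel, , drop = FALSE]
  found <- found[!duplicated(found$mutations), , drop = FALSE]
  if (nrow(found) < length(parts)) return("unlabelable")
  if (abs(sum(ddg_of(found)) - ddg_of(multi)) <= tol_kcal) "additive" else "synergistic"
}

#' Classify a ddG value
#'
#' Increasing binding affinity iff ddG > 0.5 kcal/mol, decreasing iff
#' ddG <= -0.5; the band (-0.5, 0.5] is reported as `neutral`.
#'
#' @param ddg Numeric vector, kcal/mol.
#' @return Factor with levels `decreasing`, `neutral`, `increasing`.
#' @export
classify_ddg <- function(ddg) {
  stopifnot(all(is.finite(ddg)))
  cls <- ifelse(ddg > 0.5, "increasing", ifelse(ddg <= -0.5, "decreasing", "neutral"))
  factor(cls, levels = c("decreasing", "neutral", "increasing"))
}

AFFINITY_COLS <- c("complex_id", "mutations", "kd_wt", "kd_mut", "temperature",
                   "ddg", "is_reverse", "is_non_binder", "source")

#' Read affinity records from CSV
#'
#' Schema: `complex_id`, `mutations` (semicolon dialect), `kd_wt`, `kd_mut`
#' (molar), `temperature` (K; 298 when blank), `ddg` (kcal/mol; derived from
#' the K_D pair when blank), `is_reverse`, `is_non_binder`, `source`.
#' A record carrying both a K_D pair and an inconsistent direct ddG
#' (> 1e-6 kcal/mol apart) is a schema error, reported with its line number.
#'
#' @param path CSV path.
#' @return Tibble of affinity records with `ddg` filled for binders.
#' @export
read_affinity_csv <- function(path) {
  rec <- readr::read_csv(path, col_types = readr::cols(
    complex_id = "c", mutations = "c", kd_wt = "d", kd_mut = "d",
    temperature = "d", ddg = "d", is_reverse = "l", is_non_binder = "l",
    source = "c"), progress = FALSE)
  missing_cols <- setdiff(AFFINITY_COLS, names(rec))
  if (length(missing_cols) > 0)
    stop("affinity CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  rec$temperature[is.na(rec$temperature)] <- 298
  rec$is_reverse[is.na(rec$is_reverse)] <- FALSE
  rec$is_non_binder[is.na(rec$is_non_binder)] <- FALSE
  for (i in seq_len(nrow(rec))) {
    line <- i + 1  # header line is 1
    r <- rec[i, ]
    if (r$temperature <= 0) stop("line ", line, ": nonpositive temperature")
    if (r$is_non_binder) {
      if (!is.na(r$ddg)) stop("line ", line, ": non-binder must not carry a ddG")
      next
    }
    has_kd <- !is.na(r$kd_wt) && !is.na(r$kd_mut)
    if (!has_kd && is.na(r$ddg))
      stop("line ", line, ": record needs a K_D pair or a direct ddG")
    if (has_kd && any(c(r$kd_wt, r$kd_mut) <= 0))
      stop("line ", line, ": nonpositive K_D")
    if (has_kd && !is.na(r$ddg)) {
      derived <- delta_g_from_kd(r$kd_wt, r$temperature) -
        delta_g_from_kd(r$kd_mut, r$temperature)
      if (abs(derived - r$ddg) > 1e-6)
        stop("line ", line, ": direct ddG (", r$ddg,
             ") inconsistent with K_D pair (", signif(derived, 8), ")")
    }
  }
  binder <- !rec$is_non_binder
  rec$ddg[binder] <- ddg_of(rec[binder, , drop = FALSE])
  rec
}

#' Write affinity records to CSV
#'
#' Inverse of [read_affinity_csv()] (round-trip lossless on its schema).
#'
#' @param records Affinity-record tibble.
#' @param path Output path.
#' @export
write_affinity_csv <- function(records, path) {
  readr::write_csv(records[intersect(AFFINITY_COLS, names(records))], path)
  invisible(path)
}

#' Partition curated records
#'
#' Non-binders are excluded from training and kept as a classification-only
#' evaluation partition; multi-point records form the blind test partition;
#' single-point records form the training partition.
#'
#' @param records Affinity-record tibble.
#' @return The records with a `partition` column
#'   (`train` / `blind_multi` / `non_binder`).
#' @export
curate_dataset <- function(records) {
  multi <- grepl(";", records$mutations, fixed = TRUE)
  records$partition <- ifelse(records$is_non_binder, "non_binder",
                              ifelse(multi, "blind_multi", "train"))
  key <- paste(records$complex_id, records$mutations, records$partition)
  if (anyDuplicated(key[!records$is_reverse]))
    warning("duplicate (complex, mutation) records within a partition")
  records
}
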