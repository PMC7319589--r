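# The `ab_complex` container: a tibble of heavy atoms (one row per atom) with
# an antibody/antigen chain partition carried as attributes. Keeping the atom
# table a plain tibble means every dplyr verb works on it directly.

#' Construct an antibody-antigen complex from an atom table
#'
#' @param atoms A data frame with columns `chain`, `resno`, `icode`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`. `icode` is `""` when the
#'   residue has no insertion code.
#' @param antibody_chains,antigen_chains Character vectors of chain IDs (or a
#'   single comma-separated string, e.g. `"H,L"`). Must be disjoint and
#'   non-empty.
#' @return A tibble of class `ab_complex` with an added `is_backbone` column
#'   and a `key` column (`chain.resno[icode]`) identifying each residue.
#' @export
as_complex <- function(atoms, antibody_chains, antigen_chains) {
  antibody_chains <- split_chains(antibody_chains)
  antigen_chains <- split_chains(antigen_chains)
  if (length(antibody_chains) == 0 || length(antigen_chains) == 0)
    stop("both antibody and antigen chain sets must be non-empty")
  if (length(intersect(antibody_chains, antigen_chains)) > 0)
    stop("antibody and antigen chain sets overlap: ",
         paste(intersect(antibody_chains, antigen_chains), collapse = ", "))
  need <- c("chain", "resno", "icode", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  present <- unique(atoms$chain)
  absent <- setdiff(c(antibody_chains, antigen_chains), present)
  if (length(absent) > 0)
    stop("declared chains not present in structure: ", paste(absent, collapse = ", "))
  atoms <- tibble::as_tibble(atoms)[need]
  atoms$resno <- as.integer(atoms$resno)
  atoms$is_backbone <- atoms$atom %in% BACKBONE_ATOMS
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)
  stopifnot(all(is.finite(c(atoms$x, atoms$y, atoms$z))), all(nzchar(atoms$element)))
  structure(atoms,
            antibody_chains = antibody_chains,
            antigen_chains = antigen_chains,
            class = c("ab_complex", class(tibble::tibble())))
}

split_chains <- function(x) {
  x <- unlist(strsplit(as.character(x), ",", fixed = TRUE))
  unique(trimws(x[nzchar(trimws(x))]))
}

res_key <- function(chain, resno, icode) {
  paste0(chain, ".", resno, ifelse(nzchar(icode), icode, ""))
}

#' @export
antibody_chains <- function(complex) attr(complex, "antibody_chains")

#' @export
antigen_chains <- function(complex) attr(complex, "antigen_chains")

# side ("antibody"/"antigen") of each atom row
chain_side <- function(complex) {
  ifelse(complex$chain %in% antibody_chains(complex), "antibody",
         ifelse(complex$chain %in% antigen_chains(complex), "antigen", NA))
}

#' Residue table of a complex
#'
#' One row per residue, in file order, with its chain partition side.
#'
#' @param complex An [as_complex()] object.
#' @return A tibble with `key`, `chain`, `resno`, `icode`, `resname`, `side`.
#' @export
complex_residues <- function(complex) {
  res <- dplyr::distinct(tibble::as_tibble(complex)[c("key", "chain", "resno", "icode", "resname")])
  res$side <- ifelse(res$chain %in% antibody_chains(complex), "antibody",
                     ifelse(res$chain %in% antigen_chains(complex), "antigen", NA))
  res
}

residue_atoms <- function(complex, key) {
  tibble::as_tibble(complex)[complex$key == key, , drop = FALSE]
}

# reinstate class/attrs after dplyr operations that strip them
keep_complex <- function(atoms, template) {
  as_complex(atoms, antibody_chains(template), antigen_chains(template))
}

#' @export
print.ab_complex <- function(x, ...) {
  res <- complex_residues(x)
  cat(sprintf("<ab_complex> %d atoms, %d residues | antibody: %s | antigen: %s\n",
              nrow(x), nrow(res),
              paste(antibody_chains(x), collapse = ","),
              paste(antigen_chains(x), collapse = ",")))
  NextMethod()
}
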