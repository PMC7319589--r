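# PDB I/O (via bio3d), mutation-list parsing, the backbone-preserving mutant
# builder, and interface/distance geometry.

#' Read an antibody-antigen complex from a PDB file
#'
#' Parses ATOM records of standard amino acids (model 1 only), drops
#' HETATM/waters and hydrogens, and resolves alternate locations by keeping
#' the highest-occupancy altloc (ties broken alphabetically).
#'
#' @param path Path to a PDB file.
#' @param antibody_chains,antigen_chains Chain IDs of the two sides of the
#'   complex, e.g. `"H,L"` and `"A"`.
#' @return An [as_complex()] tibble.
#' @export
read_pdb <- function(path, antibody_chains, antigen_chains) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM" & a$resid %in% names(AA1), , drop = FALSE]
  if (nrow(a) == 0) stop("no protein ATOM records in ", path)
  elem <- ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                 atom_element(a$elety), trimws(a$elesy))
  a <- a[toupper(elem) != "H" & toupper(elem) != "D", , drop = FALSE]
  a$icode <- ifelse(is.na(a$insert), "", a$insert)
  a$alt <- ifelse(is.na(a$alt), "", a$alt)
  a$o <- ifelse(is.na(a$o), 1, a$o)
  # altloc: keep the highest-occupancy record per atom, alphabetical ties,
  # preserving file order of the surviving records
  ord <- seq_len(nrow(a))
  by_occ <- order(a$chain, a$resno, a$icode, a$elety, -a$o, a$alt)
  dup <- duplicated(a[by_occ, c("chain", "resno", "icode", "elety")])
  keep_rows <- sort(ord[by_occ][!dup])
  dropped <- a[ord[by_occ][dup], , drop = FALSE]
  if (any(!nzchar(dropped$alt)))
    stop("duplicate residue/atom key after altloc resolution in ", path)
  kept <- a[keep_rows, , drop = FALSE]
  atoms <- tibble::tibble(
    chain = kept$chain, resno = as.integer(kept$resno), icode = kept$icode,
    resname = kept$resid, atom = kept$elety,
    element = toupper(ifelse(is.na(kept$elesy) | !nzchar(trimws(kept$elesy)),
                             atom_element(kept$elety), trimws(kept$elesy))),
    x = kept$x, y = kept$y, z = kept$z
  )
  as_complex(atoms, antibody_chains, antigen_chains)
}

#' Write a complex to a PDB file
#'
#' Standard ATOM records with consecutive serial numbers and TER records
#' between chains; coordinates at the format's 3-decimal precision.
#'
#' @param complex An [as_complex()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(complex, path) {
  if (nrow(complex) == 0) stop("refusing to write an empty complex")
  xyz <- as.numeric(t(coords_matrix(complex)))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", nrow(complex)),
    eleno = seq_len(nrow(complex)), elety = complex$atom,
    resid = complex$resname, chain = complex$chain,
    resno = complex$resno, insert = complex$icode,
    o = rep(1, nrow(complex)), b = rep(0, nrow(complex)),
    elesy = complex$element, chainter = TRUE, end = TRUE
  )
  invisible(path)
}

#' Parse a mutation list
#'
#' One multi-mutation per line; point mutations within a line are separated
#' by semicolons and written `CHAIN.WT<number><icode?>MT`, e.g.
#' `"H.Y33A;L.S52W"` or `"H.A100BY"` (residue 100, insertion code B).
#'
#' @param text Character vector of lines (or one string with embedded
#'   newlines).
#' @return A tibble with columns `set` (line number), `spec` (the token),
#'   `chain`, `wt`, `resno`, `icode`, `mt`. Rows sharing `set` form one
#'   multi-mutation.
#' @export
parse_mutation_list <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty mutation list")
  out <- purrr::map2_dfr(lines, seq_along(lines), function(line, i) {
    tokens <- trimws(unlist(strsplit(line, ";", fixed = TRUE)))
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0) stop("empty multi-mutation on line ", i)
    m <- stringr::str_match(tokens, "^([A-Za-z0-9])\\.([A-Z])([0-9]+)([A-Z]?)([A-Z])$")
    bad <- which(is.na(m[, 1]))
    if (length(bad) > 0)
      stop("malformed mutation token on line ", i, ": '", tokens[bad[1]], "'")
    spec <- tibble::tibble(
      set = i, spec = tokens, chain = m[, 2], wt = m[, 3],
      resno = as.integer(m[, 4]), icode = m[, 5], mt = m[, 6]
    )
    aa_three(spec$wt); aa_three(spec$mt)  # validates letters
    same <- spec$wt == spec$mt
    if (any(same))
      stop("wild-type equals mutant on line ", i, ": '", spec$spec[same][1], "'")
    site <- res_key(spec$chain, spec$resno, spec$icode)
    if (anyDuplicated(site))
      stop("duplicate mutated site on line ", i, ": ", site[duplicated(site)][1])
    spec
  })
  out
}

#' Format mutation specs back into the string dialect
#' @param specs A spec tibble as returned by [parse_mutation_list()].
#' @return One string per `set`.
#' @export
format_mutation <- function(specs) {
  tok <- paste0(specs$chain, ".", specs$wt, specs$resno, specs$icode, specs$mt)
  unname(vapply(split(tok, specs$set), paste, "", collapse = ";"))
}

#' Build a mutant structure
#'
#' Applies point mutations one at a time in list order. Backbone atoms
#' (N, CA, C, O and OXT if present) are never moved; the side chain is
#' replaced by the idealized template of the mutant residue rigidly aligned
#' on the residue's own N/CA/C backbone frame (template chi angles, no
#' rotamer search, no minimization).
#'
#' @param complex An [as_complex()] object.
#' @param specs A spec tibble (one multi-mutation; see
#'   [parse_mutation_list()]).
#' @return A new `ab_complex`.
#' @export
build_mutant <- function(complex, specs) {
  atoms <- tibble::as_tibble(complex)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    key <- res_key(s$chain, s$resno, s$icode)
    idx <- which(atoms$key == key)
    if (length(idx) == 0) stop("mutation site not found in structure: ", key)
    found <- unique(atoms$resname[idx])
    if (aa_one(found) != s$wt)
      stop("wild-type mismatch at ", key, ": expected ", s$wt,
           " (", aa_three(s$wt), "), found ", aa_one(found), " (", found, ")")
    res <- atoms[idx, ]
    bb_needed <- c("N", "CA", "C")
    if (!all(bb_needed %in% res$atom))
      stop("missing backbone atoms at ", key, ": ",
           paste(setdiff(bb_needed, res$atom), collapse = ", "))
    tmpl <- residue_template(aa_three(s$mt))
    tm <- coords_matrix(tmpl); rownames(tm) <- tmpl$atom
    rm_ <- coords_matrix(res); rownames(rm_) <- res$atom
    tr <- rigid_transform(tm[bb_needed, , drop = FALSE], rm_[bb_needed, , drop = FALSE])
    side <- tmpl[!tmpl$atom %in% BACKBONE_ATOMS, , drop = FALSE]
    keep <- res[res$atom %in% c(BACKBONE_ATOMS, "OXT"), , drop = FALSE]
    keep$resname <- aa_three(s$mt)
    new_rows <- keep
    if (nrow(side) > 0) {
      sc <- tr(coords_matrix(side))
      new_rows <- dplyr::bind_rows(keep, tibble::tibble(
        chain = s$chain, resno = s$resno, icode = s$icode,
        resname = aa_three(s$mt), atom = side$atom, element = side$element,
        x = sc[, 1], y = sc[, 2], z = sc[, 3],
        is_backbone = FALSE, key = key
      ))
    }
    atoms <- dplyr::bind_rows(
      if (min(idx) > 1) atoms[seq_len(min(idx) - 1), ],
      new_rows,
      if (max(idx) < nrow(atoms)) atoms[(max(idx) + 1):nrow(atoms), ]
    )
  }
  keep_complex(atoms, complex)
}

#' Interface residues of a complex
#'
#' A residue is interfacial iff any of its heavy atoms lies within `cutoff`
#' of any heavy atom of the opposite partition.
#'
#' @param complex An [as_complex()] object.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5.0).
#' @return A tibble of interfacial residues (`key`, `chain`, `resno`,
#'   `icode`, `resname`, `side`, `dist_partner`), possibly empty.
#' @export
interface_residues <- function(complex, cutoff = 5) {
  stopifnot(cutoff > 0)
  side <- chain_side(complex)
  ab <- coords_matrix(complex)[side == "antibody", , drop = FALSE]
  ag <- coords_matrix(complex)[side == "antigen", , drop = FALSE]
  d <- cross_dist(ab, ag)
  ab_min <- apply(d, 1, min); ag_min <- apply(d, 2, min)
  res_min <- c(tapply(ab_min, complex$key[side == "antibody"], min),
               tapply(ag_min, complex$key[side == "antigen"], min))
  res <- complex_residues(complex)
  res$dist_partner <- unname(res_min[res$key])
  res[!is.na(res$dist_partner) & res$dist_partner <= cutoff, , drop = FALSE]
}

#' Minimum heavy-atom distance between two residues
#'
#' @param complex An [as_complex()] object.
#' @param site_a,site_b Residue keys (`chain.resno[icode]`).
#' @return Distance in Angstrom; 0 for a site against itself.
#' @export
min_heavy_distance <- function(complex, site_a, site_b) {
  xa <- coords_matrix(complex)[complex$key == site_a, , drop = FALSE]
  xb <- coords_matrix(complex)[complex$key == site_b, , drop = FALSE]
  if (nrow(xa) == 0) stop("unknown site: ", site_a)
  if (nrow(xb) == 0) stop("unknown site: ", site_b)
  if (site_a == site_b) return(0)
  min(cross_dist(xa, xb))
}

# Minimum heavy-atom distance from a residue to the opposite partition.
dist_to_partner <- function(complex, key) {
  side <- chain_side(complex)
  row_side <- unique(side[complex$key == key])
  if (length(row_side) != 1 || is.na(row_side)) stop("unknown or unpartitioned site: ", key)
  xa <- coords_matrix(complex)[complex$key == key, , drop = FALSE]
  xb <- coords_matrix(complex)[side != row_side & !is.na(side), , drop = FALSE]
  min(cross_dist(xa, xb))
}
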