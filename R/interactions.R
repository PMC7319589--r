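# Typed non-covalent contact detection (heavy-atom geometric rules in the
# style of Arpeggio's categories), Shrake-Rupley solvent accessible surface
# area, and wild-type -> mutant delta features.

CONTACT_TYPES <- c("hbond", "ionic", "aromatic", "cation_pi", "hydrophobic",
                   "vdw", "polar")

# contact rule thresholds (Angstrom), frozen as a config block
contact_config <- function() {
  list(hbond_min = 2.5, hbond_max = 3.5, ionic_max = 4.0, aromatic_max = 6.0,
       cation_pi_max = 6.0, hydrophobic_max = 4.5, vdw_slack = 0.5,
       polar_max = 3.5)
}

# Bondi van der Waals radii by element (Angstrom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

POSITIVE_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                       HIS = c("ND1", "NE2"))
NEGATIVE_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

atom_in_set <- function(resname, atom, set) {
  idx <- match(resname, names(set))
  out <- logical(length(resname))
  ok <- which(!is.na(idx))
  for (k in ok) out[k] <- atom[k] %in% set[[idx[k]]]
  out
}

# Covalent bond inference by distance; used only to exclude 1-2/1-3 pairs
# from contact typing. Heavy-atom bonds: < 1.9 A (2.2 if either atom is S).
infer_bonds <- function(complex) {
  xyz <- coords_matrix(complex)
  d <- cross_dist(xyz, xyz)
  lim <- ifelse(outer(complex$element == "S", complex$element == "S", `|`), 2.2, 1.9)
  sel <- upper.tri(d) & d < lim & d > 0.5
  cbind(row(d)[sel], col(d)[sel])
}

# pair keys ("i:j", i < j) of covalently bonded (1-2) and angle (1-3) pairs
adjacency_13 <- function(bonds, n) {
  if (nrow(bonds) == 0) return(character())
  adj <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
  k12 <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]), sep = ":")
  k13 <- unlist(lapply(adj, function(nb) {
    if (length(nb) < 2) return(character())
    cmb <- utils::combn(sort(nb), 2)
    paste(cmb[1, ], cmb[2, ], sep = ":")
  }), use.names = FALSE)
  unique(c(k12, k13))
}

#' Detect typed non-covalent contacts
#'
#' Deterministic heavy-atom geometric rules: hydrogen bond (donor-bearing
#' N/O/S to acceptor N/O, 2.5-3.5 A), ionic (opposite formal charges <= 4 A),
#' aromatic-aromatic (ring centroids <= 6 A), cation-pi (charged group to
#' ring centroid <= 6 A), hydrophobic (apolar C-C <= 4.5 A), polar
#' (donor/acceptor N/O/S pair <= 3.5 A not hydrogen-bondable), van der Waals
#' (separation <= sum of vdW radii + 0.5 A, not otherwise typed). Covalently
#' bonded and 1-3 pairs are excluded.
#'
#' @param complex An [as_complex()] object.
#' @param table A [pharmacophore_table()] (donor/acceptor/apolar typing).
#' @return A tibble: `key1`, `atom1`, `key2`, `atom2`, `type`, `distance`,
#'   `interfacial`.
#' @export
detect_contacts <- function(complex, table = pharmacophore_table()) {
  n <- nrow(complex)
  xyz <- coords_matrix(complex)
  cm <- class_matrix(complex$resname, complex$atom, table)
  donor <- cm[, "donor"] == 1 & complex$element %in% c("N", "O", "S")
  acceptor <- cm[, "acceptor"] == 1 & complex$element %in% c("N", "O")
  apolar <- cm[, "hydrophobic"] == 1 & complex$element == "C"
  pos <- atom_in_set(complex$resname, complex$atom, POSITIVE_ATOMS)
  neg <- atom_in_set(complex$resname, complex$atom, NEGATIVE_ATOMS) |
    complex$atom == "OXT"
  polar_at <- (donor | acceptor) & complex$element %in% c("N", "O", "S")
  side <- chain_side(complex)
  cfg <- contact_config()

  d <- cross_dist(xyz, xyz)
  radsum <- outer(vdw_radius(complex$element), vdw_radius(complex$element), `+`)
  cand <- upper.tri(d) & d <= pmax(radsum + cfg$vdw_slack, cfg$ionic_max)
  # exclude bonded and 1-3 pairs
  excl <- adjacency_13(infer_bonds(complex), n)
  ii <- row(d)[cand]; jj <- col(d)[cand]
  keep <- !(paste(pmin(ii, jj), pmax(ii, jj), sep = ":") %in% excl)
  ii <- ii[keep]; jj <- jj[keep]
  dd <- d[cbind(ii, jj)]

  type <- character(length(ii))
  is_hb <- ((donor[ii] & acceptor[jj]) | (donor[jj] & acceptor[ii])) &
    dd >= cfg$hbond_min & dd <= cfg$hbond_max
  is_ionic <- ((pos[ii] & neg[jj]) | (pos[jj] & neg[ii])) & dd <= cfg$ionic_max
  is_polar <- polar_at[ii] & polar_at[jj] & dd <= cfg$polar_max & !is_hb
  is_phob <- apolar[ii] & apolar[jj] & dd <= cfg$hydrophobic_max
  is_vdw <- dd <= radsum[cbind(ii, jj)] + cfg$vdw_slack &
    !(is_hb | is_ionic | is_polar | is_phob)

  res <- tibble::tibble(
    i = rep(ii, 5)[c(is_hb, is_ionic, is_polar, is_phob, is_vdw)],
    j = rep(jj, 5)[c(is_hb, is_ionic, is_polar, is_phob, is_vdw)],
    type = rep(c("hbond", "ionic", "polar", "hydrophobic", "vdw"),
               c(sum(is_hb), sum(is_ionic), sum(is_polar), sum(is_phob), sum(is_vdw)))
  )
  out <- tibble::tibble(
    key1 = complex$key[res$i], atom1 = complex$atom[res$i],
    key2 = complex$key[res$j], atom2 = complex$atom[res$j],
    type = res$type, distance = d[cbind(res$i, res$j)],
    interfacial = !is.na(side[res$i]) & !is.na(side[res$j]) &
      side[res$i] != side[res$j]
  )
  dplyr::bind_rows(out, ring_contacts(complex, pos, cfg)) |>
    dplyr::arrange(.data$type, .data$key1, .data$atom1, .data$key2, .data$atom2)
}

# aromatic-aromatic and cation-pi contacts via ring centroids
ring_contacts <- function(complex, pos, cfg) {
  res <- complex_residues(complex)
  rings <- purrr::map_dfr(seq_len(nrow(res)), function(r) {
    defs <- AROMATIC_RINGS[[res$resname[r]]]
    if (is.null(defs)) return(tibble::tibble())
    purrr::imap_dfr(defs, function(atoms, k) {
      ra <- complex[complex$key == res$key[r] & complex$atom %in% atoms, , drop = FALSE]
      if (nrow(ra) < length(atoms)) return(tibble::tibble())
      tibble::tibble(key = res$key[r], ring = k, side = res$side[r],
                     cx = mean(ra$x), cy = mean(ra$y), cz = mean(ra$z))
    })
  })
  out <- tibble::tibble()
  if (nrow(rings) >= 2) {
    m <- cbind(rings$cx, rings$cy, rings$cz)
    d <- cross_dist(m, m)
    sel <- which(upper.tri(d) & d <= cfg$aromatic_max, arr.ind = TRUE)
    sel <- sel[rings$key[sel[, 1]] != rings$key[sel[, 2]], , drop = FALSE]
    if (nrow(sel) > 0)
      out <- tibble::tibble(
        key1 = rings$key[sel[, 1]], atom1 = paste0("ring", rings$ring[sel[, 1]]),
        key2 = rings$key[sel[, 2]], atom2 = paste0("ring", rings$ring[sel[, 2]]),
        type = "aromatic", distance = d[sel],
        interfacial = rings$side[sel[, 1]] != rings$side[sel[, 2]])
  }
  if (nrow(rings) >= 1 && any(pos)) {
    side <- chain_side(complex)
    pxyz <- coords_matrix(complex)[pos, , drop = FALSE]
    pk <- complex$key[pos]; pa <- complex$atom[pos]; ps <- side[pos]
    d <- cross_dist(pxyz, cbind(rings$cx, rings$cy, rings$cz))
    sel <- which(d <= cfg$cation_pi_max, arr.ind = TRUE)
    sel <- sel[pk[sel[, 1]] != rings$key[sel[, 2]], , drop = FALSE]
    if (nrow(sel) > 0)
      out <- dplyr::bind_rows(out, tibble::tibble(
        key1 = pk[sel[, 1]], atom1 = pa[sel[, 1]],
        key2 = rings$key[sel[, 2]], atom2 = paste0("ring", rings$ring[sel[, 2]]),
        type = "cation_pi", distance = d[sel],
        interfacial = ps[sel[, 1]] != rings$side[sel[, 2]]))
  }
  out
}

#' Per-type contact counts in three scopes
#'
#' @param contacts A [detect_contacts()] tibble.
#' @param sites Residue keys of the mutated sites (for the
#'   `involving-mutated-sites` scope); may be empty.
#' @return A tibble `type` x (`all`, `interfacial`, `sites`) including
#'   zero rows for absent types.
#' @export
summarize_contacts <- function(contacts, sites = character()) {
  purrr::map_dfr(CONTACT_TYPES, function(tp) {
    sub <- contacts[contacts$type == tp, , drop = FALSE]
    tibble::tibble(
      type = tp, all = nrow(sub), interfacial = sum(sub$interfacial),
      sites = sum(sub$key1 %in% sites | sub$key2 %in% sites)
    )
  })
}

#' Contact-count deltas between wild-type and mutant
#'
#' @param wt,mt Complexes sharing residue keys except mutated side chains.
#' @param sites Mutated residue keys.
#' @param table A [pharmacophore_table()].
#' @return Tibble `type` x signed deltas (`all`, `interfacial`, `sites`),
#'   mutant minus wild-type.
#' @export
delta_contacts <- function(wt, mt, sites, table = pharmacophore_table()) {
  if (!setequal(unique(wt$key), unique(mt$key)))
    stop("wild-type and mutant structures have mismatched residue keys")
  sw <- summarize_contacts(detect_contacts(wt, table), sites)
  sm <- summarize_contacts(detect_contacts(mt, table), sites)
  tibble::tibble(type = sw$type, all = sm$all - sw$all,
                 interfacial = sm$interfacial - sw$interfacial,
                 sites = sm$sites - sw$sites)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Deterministic sphere sampling on a golden-spiral lattice with Bondi
#' element radii.
#'
#' @param complex An [as_complex()] object (or any atom tibble with
#'   `key`, `element`, coordinates).
#' @param probe_radius Probe radius, Angstrom (water: 1.4).
#' @param n_points Sample points per atom (>= 60).
#' @return A tibble of per-residue areas (`key`, `area`) with attributes
#'   `total`, `probe_radius`, `n_points`, and per-atom areas in `atom_area`.
#' @export
sasa <- function(complex, probe_radius = 1.4, n_points = 960) {
  stopifnot(probe_radius > 0, n_points >= 60)
  xyz <- coords_matrix(complex)
  n <- nrow(xyz)
  rad <- vdw_radius(complex$element) + probe_radius
  pts <- golden_spiral_points(n_points)
  d <- cross_dist(xyz, xyz)
  reach <- outer(rad, rad, `+`)
  atom_area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < reach[i, ] & seq_len(n) != i)
    if (length(nb) > 0) {
      p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
      dp <- cross_dist(p, xyz[nb, , drop = FALSE])
      occluded <- rowSums(dp < rep(rad[nb], each = n_points)) > 0
      frac <- sum(!occluded) / n_points
    } else frac <- 1
    atom_area[i] <- frac * 4 * pi * rad[i]^2
  }
  per_res <- tibble::tibble(key = unique(complex$key))
  per_res$area <- as.numeric(tapply(atom_area, complex$key, sum)[per_res$key])
  structure(per_res, total = sum(atom_area), probe_radius = probe_radius,
            n_points = n_points, atom_area = atom_area)
}

#' Total SASA of a [sasa()] result
#' @param s A [sasa()] tibble.
#' @export
sasa_total <- function(s) attr(s, "total")

#' SASA deltas between wild-type and mutant
#'
#' @param wt,mt Complexes sharing residue keys except mutated side chains.
#' @param sites Mutated residue keys.
#' @param probe_radius,n_points Passed to [sasa()].
#' @return A one-row tibble: `site` (summed per-site delta), `total`
#'   (complex-total delta) and `buried` (delta of interface-buried area =
#'   sum of partition SASAs minus complex SASA), all mutant minus wild-type,
#'   Angstrom^2.
#' @export
delta_sasa <- function(wt, mt, sites, probe_radius = 1.4, n_points = 960) {
  if (!setequal(unique(wt$key), unique(mt$key)))
    stop("wild-type and mutant structures have mismatched residue keys")
  one <- function(cx) {
    s <- sasa(cx, probe_radius, n_points)
    side <- chain_side(cx)
    ab <- sasa(cx[side == "antibody", , drop = FALSE], probe_radius, n_points)
    ag <- sasa(cx[side == "antigen", , drop = FALSE], probe_radius, n_points)
    list(site = sum(s$area[s$key %in% sites]), total = sasa_total(s),
         buried = sasa_total(ab) + sasa_total(ag) - sasa_total(s))
  }
  w <- one(wt); m <- one(mt)
  tibble::tibble(site = m$site - w$site, total = m$total - w$total,
                 buried = m$buried - w$buried)
}
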