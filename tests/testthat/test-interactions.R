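# geometric fixture: a lysine and a glutamate with NZ-OE1 placed at 3.0 A
salt_bridge_complex <- function() {
  lys <- abddg:::build_extended_chain("KAAAA", "H")
  glu <- abddg:::build_extended_chain("EAAAA", "A")
  nz <- unlist(lys[lys$atom == "NZ", c("x", "y", "z")])
  oe1 <- unlist(glu[glu$atom == "OE1", c("x", "y", "z")])
  shift <- nz + c(3, 0, 0) - oe1
  glu$x <- glu$x + shift[1]; glu$y <- glu$y + shift[2]; glu$z <- glu$z + shift[3]
  as_complex(dplyr::bind_rows(lys, glu), "H", "A")
}

test_that("a constructed salt bridge is typed ionic (and hydrogen-bondable)", {
  cx <- salt_bridge_complex()
  ct <- detect_contacts(cx)
  ionic <- ct[ct$type == "ionic", ]
  expect_equal(nrow(ionic), 1)
  expect_setequal(c(ionic$atom1, ionic$atom2), c("NZ", "OE1"))
  expect_equal(ionic$distance, 3, tolerance = 1e-6)
  expect_true(ionic$interfacial)
  hb <- ct[ct$type == "hbond", ]
  expect_true(any((hb$atom1 == "NZ" & hb$atom2 == "OE1") |
                    (hb$atom1 == "OE1" & hb$atom2 == "NZ")))
})

test_that("atoms beyond every cutoff yield no contact of any type", {
  expect_equal(nrow(detect_contacts(atom_pair_complex(8))), 0)
})

test_that("every contact distance lies inside its type window", {
  ct <- detect_contacts(fix_complex())
  windows <- list(hbond = c(2.5, 3.5), ionic = c(0, 4), aromatic = c(0, 6),
                  cation_pi = c(0, 6), hydrophobic = c(0, 4.5),
                  polar = c(0, 3.5), vdw = c(0, 2 * 1.8 + 0.5))
  for (tp in unique(ct$type)) {
    w <- windows[[tp]]
    expect_true(all(ct$distance[ct$type == tp] >= w[1] &
                      ct$distance[ct$type == tp] <= w[2]), info = tp)
  }
})

test_that("contacts are invariant under rigid motion and chain relabeling", {
  cx <- fix_complex()
  a <- summarize_contacts(detect_contacts(cx))
  b <- summarize_contacts(detect_contacts(rotate_complex(cx, 3)))
  expect_equal(a, b, tolerance = 1e-9)
  swapped <- as_complex(tibble::as_tibble(cx), "A", "H")
  expect_equal(summarize_contacts(detect_contacts(swapped))$all, a$all)
})

test_that("contact deltas vanish on identity and are exactly antisymmetric", {
  cx <- fix_complex()
  z <- delta_contacts(cx, cx, "H.2")
  expect_true(all(z$all == 0 & z$interfacial == 0 & z$sites == 0))
  mt <- build_mutant(cx, parse_mutation_list("H.K2A"))
  fwd <- delta_contacts(cx, mt, "H.2")
  rev <- delta_contacts(mt, cx, "H.2")
  expect_equal(fwd$all, -rev$all)
  expect_equal(fwd$interfacial, -rev$interfacial)
  expect_equal(fwd$sites, -rev$sites)
  expect_error(delta_contacts(cx, cx[cx$key != "H.1", ], "H.2"), "mismatched")
})

test_that("an interface lysine-to-alanine mutation removes its salt bridge", {
  cx <- salt_bridge_complex()
  mt <- build_mutant(cx, parse_mutation_list("H.K1A"))
  d <- delta_contacts(cx, mt, "H.1")
  expect_equal(d$interfacial[d$type == "ionic"], -1)
})

test_that("SASA matches the isolated-sphere closed form and encloses to zero", {
  one <- atom_pair_complex(500)
  s <- sasa(one, probe_radius = 1.4, n_points = 960)
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(s$area[1], exact, tolerance = 0.01)
  # atom fully enclosed by a shell of atoms
  shell_pts <- abddg:::golden_spiral_points(60) * 2.2
  shell <- as_complex(tibble::tibble(
    chain = c("H", rep("A", 60)), resno = c(1L, seq_len(60)), icode = "",
    resname = "ALA", atom = "CB", element = "C",
    x = c(0, shell_pts[, 1]), y = c(0, shell_pts[, 2]), z = c(0, shell_pts[, 3])
  ), "H", "A")
  sh <- sasa(shell, 1.4, 960)
  expect_equal(sh$area[sh$key == "H.1"], 0)
})

test_that("SASA converges with sampling density and is rotation-stable", {
  cx <- fix_complex()
  a <- sasa_total(sasa(cx, 1.4, 960))
  b <- sasa_total(sasa(cx, 1.4, 10000))
  expect_lt(abs(a - b) / b, 0.02)
  r <- sasa_total(sasa(rotate_complex(cx, 5), 1.4, 960))
  expect_lt(abs(a - r) / a, 0.005)
  expect_true(all(sasa(cx, 1.4, 960)$area >= 0))
})

test_that("SASA deltas: identity is zero; X->G frees no side-chain area", {
  cx <- fix_complex()
  z <- delta_sasa(cx, cx, "H.2", n_points = 240)
  expect_equal(unlist(z), c(site = 0, total = 0, buried = 0))
  # removing a tryptophan side chain at a surface site shrinks the
  # residue's own area, consistent with the isolated-residue computation
  mt <- build_mutant(cx, parse_mutation_list("H.W4G"))
  d <- delta_sasa(cx, mt, "H.4", n_points = 240)
  iso_wt <- sasa(cx[cx$key == "H.4", ], 1.4, 240)
  iso_mt <- sasa(mt[mt$key == "H.4", ], 1.4, 240)
  iso_delta <- sasa_total(iso_mt) - sasa_total(iso_wt)
  expect_lt(iso_delta, 0)
  expect_lt(d$site, 0)
})

test_that("buried area equals brute-force recomputation from three SASA calls", {
  cx <- fix_complex()
  mt <- build_mutant(cx, parse_mutation_list("H.K2A"))
  d <- delta_sasa(cx, mt, "H.2", n_points = 240)
  side <- abddg:::chain_side(mt)
  brute <- function(cc) {
    s <- abddg:::chain_side(cc)
    sasa_total(sasa(cc[s == "antibody", ], 1.4, 240)) +
      sasa_total(sasa(cc[s == "antigen", ], 1.4, 240)) -
      sasa_total(sasa(cc, 1.4, 240))
  }
  expect_equal(d$buried, brute(mt) - brute(cx), tolerance = 1e-9)
})
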