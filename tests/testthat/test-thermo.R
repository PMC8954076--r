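ref <- reference_enthalpies()
delta <- betashape:::cycle_delta(ref)

test_that("the cycle offset delta follows from the reference enthalpies", {
  # delta = H(H.) - H(H+) - H(e-) = -314.65 + 259.00 + 55.61
  expect_equal(delta, -0.04, tolerance = 1e-12)
})

test_that("descriptors invert the synthetic construction exactly", {
  for (seed in c(1L, 2L)) {
    tg <- betashape:::with_seed(seed, data.frame(
      site = paste0("S", 1:4),
      BDE = runif(4, 60, 100), PA = runif(4, 5, 40)))
    IP <- betashape:::with_seed(seed + 10L, runif(1, 60, 90))
    sp <- synth_enthalpy_table(tg, IP, ref, base_H = -500)
    tab <- compute_descriptors(sp, ref)
    expect_equal(tab$site, tg$site)
    expect_lt(max(abs(tab$BDE - tg$BDE)), 1e-10)
    expect_lt(max(abs(tab$PA - tg$PA)), 1e-10)
    expect_lt(max(abs(tab$IP - IP)), 1e-10)
    # ETE and PDE follow from the identities
    expect_lt(max(abs(tab$ETE - (tg$BDE - tg$PA - delta))), 1e-10)
    expect_lt(max(abs(tab$PDE - (tg$BDE - IP - delta))), 1e-10)
  }
})

test_that("a site with H(ArO.) + H(H.) = H(ArOH) has BDE zero", {
  sp <- data.frame(compound = "z", site = c("parent", "s", "s", "parent"),
                   role = c("parent", "radical", "anion",
                            "cation_radical"),
                   H = c(-100, -100 - ref$H_hydrogen_atom, -120, -30))
  tab <- compute_descriptors(sp, ref)
  expect_equal(tab$BDE, 0, tolerance = 1e-12)
})

test_that("hartree input converts at 627.5095 and round-trips", {
  expect_equal(kcal_to_hartree(hartree_to_kcal(1.2345)), 1.2345,
               tolerance = 1e-12)
  tg <- data.frame(site = "s1", BDE = 84.8, PA = 15.0)
  sp <- synth_enthalpy_table(tg, IP = 74.1, ref)
  sph <- sp
  sph$H <- kcal_to_hartree(sp$H)
  sph$unit <- "hartree"
  t1 <- compute_descriptors(sp, ref)
  t2 <- compute_descriptors(sph, ref)
  expect_equal(as.data.frame(t1), as.data.frame(t2), tolerance = 1e-9)
  spbad <- sp
  spbad$unit[2] <- "furlongs"
  expect_error(compute_descriptors(spbad, ref), "unit")
})

test_that("missing species yield NA cells with a warning", {
  sp <- data.frame(compound = "z", site = c("parent", "s1", "s1", "s2"),
                   role = c("parent", "radical", "anion", "anion"),
                   H = c(-100, -400, -350, -360))
  expect_warning(tab <- compute_descriptors(sp, ref), "missing")
  expect_true(is.na(tab$IP[1]))              # no cation_radical supplied
  expect_true(is.na(tab$BDE[tab$site == "s2"]))
  expect_false(is.na(tab$PA[tab$site == "s2"]))
})

test_that("cycle residuals are machine-zero internally, flag corruption", {
  tg <- data.frame(site = c("a", "b"), BDE = c(80, 90), PA = c(12, 20))
  tab <- compute_descriptors(synth_enthalpy_table(tg, IP = 70, ref), ref)
  res <- cycle_residuals(tab, ref, tol = 1e-10)
  expect_true(all(res$splet_ok & res$setpt_ok))
  expect_lt(max(abs(c(res$splet_residual, res$setpt_residual))), 1e-10)
  # deliberately corrupt one printed-style cell
  bad <- as.data.frame(tab)
  bad$PDE[2] <- bad$PDE[2] + 4.6
  res2 <- cycle_residuals(as_descriptor_table(bad, reference = ref))
  expect_equal(res2$setpt_ok, c(TRUE, FALSE))
  expect_true(all(res2$splet_ok))
})

test_that("published tables round to the cycle within 0.15 kcal/mol", {
  # one-decimal rounding of each of three terms bounds the residual
  bn <- betalain_descriptors("Bn")
  res <- cycle_residuals(as_descriptor_table(bn, "Bn", ref))
  expect_true(all(res$splet_ok & res$setpt_ok))
  expect_lt(max(abs(res$setpt_residual)), 0.15)
})

test_that("sites rank ascending by PA with stable tie handling", {
  bd <- as_descriptor_table(betalain_descriptors("Bd"), "Bd", ref)
  expect_equal(as.vector(rank_sites(bd)),
               c("C17", "C15", "C2", "C6", "N16", "C5"))
  single <- as_descriptor_table(data.frame(site = "only", PA = 10))
  expect_equal(as.vector(rank_sites(single)), "only")
  tied <- as_descriptor_table(data.frame(site = c("x", "y"),
                                         PA = c(5, 5)))
  r <- rank_sites(tied)
  expect_equal(as.vector(r), c("x", "y"))   # input order preserved
  expect_true(attr(r, "ties"))
  expect_error(rank_sites(single, by = "BDE"), "absent")
})

test_that("mechanism classification compares first-step descriptors", {
  isobd <- as_descriptor_table(betalain_descriptors("IsoBd"), "IsoBd",
                               ref)
  m <- classify_mechanism(isobd)
  expect_equal(m$mechanism, "SPLET")
  expect_equal(m$site, "C17")
  expect_equal(m$values[["SPLET"]], 10.8)
  # forced SET-PT ordering
  synth <- as_descriptor_table(data.frame(site = "s", BDE = 80, PA = 30,
                                          IP = 20))
  expect_equal(classify_mechanism(synth)$mechanism, "SET-PT")
  # documented tie rule: PA = IP resolves to SPLET, tie reported
  tie <- as_descriptor_table(data.frame(site = "s", BDE = 80, PA = 25,
                                        IP = 25))
  mt <- classify_mechanism(tie)
  expect_equal(mt$mechanism, "SPLET")
  expect_true(mt$tie)
  none <- as_descriptor_table(data.frame(site = "s", ETE = 60))
  expect_error(classify_mechanism(none), "at least one")
})

test_that("PA/RD concordance detects order preservation and reversal", {
  desc <- as_descriptor_table(data.frame(site = c("A1", "B2", "C3"),
                                         PA = c(10, 12, 15)))
  conc <- rd_pa_concordance(desc, data.frame(site = c("A1", "B2", "C3"),
                                             rd = c(0.01, 0.02, 0.03)))
  expect_equal(conc$concordance, 1)
  expect_equal(nrow(conc$discordant), 0)
  rev <- rd_pa_concordance(desc, data.frame(site = c("A1", "B2", "C3"),
                                            rd = c(0.03, 0.02, 0.01)))
  expect_equal(rev$concordance, -1)
  expect_equal(nrow(rev$discordant), 3)
  expect_error(rd_pa_concordance(desc, data.frame(site = "A1", rd = 0.1)),
               "fewer than 2")
})

test_that("published IsoBd carboxyl anions are fully concordant", {
  isobd <- as_descriptor_table(betalain_descriptors("IsoBd"), "IsoBd",
                               ref)
  rdtab <- betalain_rd("IsoBd")
  carboxyl <- rdtab[rdtab$site %in% c("C2", "C15", "C17"),
                    c("label", "rd")]
  conc <- rd_pa_concordance(isobd, carboxyl)   # labels like "IsoBdAC17"
  expect_equal(conc$n_sites, 3)
  expect_equal(conc$concordance, 1)
})
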