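test_that("farthest_pair is the exhaustive maximum with the tie rule", {
  line <- molecule(cbind(c(0, 1, 3), 0, 0), rep("C", 3))
  fp <- farthest_pair(line)
  expect_equal(c(fp$i, fp$j), c(1L, 3L))
  expect_equal(fp$distance, 3)
  # unit square: two diagonals tie; smallest index pair wins
  sq <- molecule(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                 rep("C", 4))
  fps <- farthest_pair(sq)
  expect_equal(c(fps$i, fps$j), c(1L, 3L))
  expect_equal(fps$distance, sqrt(2))
  # 50 random atoms vs brute-force double loop
  m <- random_molecule(50, seed = 31)
  fp50 <- farthest_pair(m)
  best <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    d <- sqrt(sum((m$coords[i, ] - m$coords[j, ])^2))
    if (d > best) best <- d
  }
  expect_equal(fp50$distance, best, tolerance = 1e-12)
})

test_that("canonical template orders variances and is proper", {
  m <- random_molecule(9, seed = 21)
  ct <- canonical_template(m)
  v <- ct$frame$axis_variances
  expect_true(v[1] >= v[2] && v[2] >= v[3])
  expect_equal(det(ct$frame$rotation), 1, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(ct$template$coords))), 1e-10)
  # variances equal the covariance eigenvalues computed independently
  ev <- sort(eigen(cov(sweep(m$coords, 2, colMeans(m$coords))),
                   symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(unname(v), ev, tolerance = 1e-10)
  # sign conventions as documented
  expect_lte(ct$template$coords[ct$frame$baseline[1], 1], 0)
  jm <- which.max(abs(ct$template$coords[, 2]))
  expect_gt(ct$template$coords[jm, 2], 0)
})

test_that("canonical template is idempotent and rigid-motion invariant", {
  m <- random_molecule(10, seed = 22)
  ct <- canonical_template(m)
  again <- canonical_template(ct$template)
  expect_lt(max(abs(again$template$coords - ct$template$coords)), 1e-8)
  expect_lt(max(abs(again$frame$rotation - diag(3))), 1e-8)
  expect_lt(max(abs(again$frame$translation)), 1e-8)
  for (seed in 1:20) {                 # full 100-motion sweep: acceptance
    g <- transform_molecule(m, random_rotation(seed),
                            translation = c(seed, -2 * seed, 5))
    expect_lt(max(abs(canonical_template(g)$template$coords -
                        ct$template$coords)), 1e-8)
  }
  # scale equivariance: canonical coordinates scale exactly, no
  # normalization sneaks in
  s3 <- canonical_template(transform_molecule(m, scale = 3))
  expect_lt(max(abs(s3$template$coords - 3 * ct$template$coords)), 1e-8)
})

test_that("no reflection can enter: chirality survives the frame", {
  ch <- chiral_fixture()
  a <- canonical_template(ch)$template
  b <- canonical_template(mirror_of(ch))$template
  expect_gt(riemannian_distance(a, b)$rd, 1e-3)
  expect_lt(riemannian_distance(a, b, mode = "allow_reflection")$rd,
            1e-9)
})

test_that("variance ties fall back to the baseline axis with a warning", {
  sq <- molecule(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                 rep("C", 4))
  expect_warning(ct <- canonical_template(sq), "tie")
  expect_equal(det(ct$frame$rotation), 1, tolerance = 1e-10)
  # baseline atoms land on the x axis
  y <- ct$template$coords
  expect_lt(max(abs(y[c(1, 3), 2:3])), 1e-9)
})

test_that("the rotation ensemble is exact and rigid", {
  m <- random_molecule(8, seed = 23)
  tpl <- canonical_template(m)$template
  ens <- rotation_ensemble(tpl)
  expect_s3_class(ens, "rotation_ensemble")
  expect_equal(ens$tags, c("none", "xy90", "xy180", "xy270", "xz90",
                           "xz180", "xz270", "yz90", "yz180", "yz270"))
  expect_identical(ens$members$none$coords, tpl$coords)
  # group closure: applying the xy90 rotation four times is the identity
  Rz <- betashape:::.exact_rotation(3L, 90L)
  cc <- colMeans(tpl$coords)
  x <- tpl$coords
  for (i in 1:4) x <- sweep(sweep(x, 2, cc) %*% t(Rz), 2, cc, "+")
  expect_equal(max(abs(x - tpl$coords)), 0)
  # xy180 equals xy90 composed with itself
  once <- sweep(sweep(ens$members$xy90$coords, 2, cc) %*% t(Rz), 2, cc,
                "+")
  expect_equal(max(abs(once - ens$members$xy180$coords)), 0)
  # rigidity: common centroid and identical distance multisets
  dref <- sort(as.vector(dist(tpl$coords)))
  for (tag in ens$tags) {
    mem <- ens$members[[tag]]
    expect_equal(colMeans(mem$coords), cc, tolerance = 1e-12)
    expect_equal(sort(as.vector(dist(mem$coords))), dref,
                 tolerance = 1e-12)
  }
})

test_that("emit_docking_job writes ligands, configs and a manifest", {
  outdir <- withr::local_tempdir()
  receptor <- file.path(outdir, "receptor.pdb")
  write_structure(random_molecule(6, seed = 1), receptor, "pdb")
  tpl <- canonical_template(random_molecule(8, seed = 24))$template
  ens <- rotation_ensemble(tpl)
  jobdir <- file.path(outdir, "job")
  manifest <- emit_docking_job(ens, receptor = receptor, outdir = jobdir)
  expect_equal(nrow(manifest), 10L)
  expect_false(anyDuplicated(manifest$tag) > 0)
  expect_true(all(file.exists(manifest$ligand)))
  expect_true(all(file.exists(manifest$config)))
  expect_true(file.exists(file.path(jobdir, "manifest.tsv")))
  # default grid box: the xanthine-oxidase active-site values
  cfg <- readLines(manifest$config[1])
  expect_true(all(c("center_x = 26", "center_y = 10", "center_z = 118",
                    "size_x = 20", "size_y = 20", "size_z = 20")
                  %in% cfg))
  # written ligand coordinates match the in-memory member (pdb precision)
  lig <- read_structure(manifest$ligand[manifest$tag == "xz180"])
  expect_lt(max(abs(lig$coords - ens$members$xz180$coords)), 5e-4)
  expect_error(emit_docking_job(ens, receptor = "nope.pdb",
                                outdir = jobdir), "receptor")
})

test_that("collate_scores picks the best pose per member", {
  dirp <- withr::local_tempdir()
  mklog <- function(tag, affs) {
    p <- file.path(dirp, paste0(tag, ".log"))
    writeLines(c("mode |   affinity | dist from best mode",
                 "-----+------------+--------------------",
                 sprintf("%4d   %10.1f      0.000      0.000",
                         seq_along(affs), affs)), p)
    p
  }
  flat <- vapply(sprintf("t%02d", 1:10), mklog,
                 FUN.VALUE = "", affs = c(-7.5, -7.5))
  tab <- collate_scores(flat)
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$best_affinity == -7.5))
  expect_equal(attr(tab, "summary")$spread, 0)
  mixed <- c(a = mklog("a", c(-8.1, -7.2)), b = mklog("b", c(-6.9, -7.4)))
  tab2 <- collate_scores(mixed)
  expect_equal(tab2$best_affinity[tab2$tag == "a"], -8.1)
  expect_equal(tab2$best_affinity[tab2$tag == "b"], -7.4)
  expect_equal(attr(tab2, "summary")$min, -8.1)
  expect_equal(attr(tab2, "summary")$spread, 0.7, tolerance = 1e-12)
  # docked-PDBQT REMARK records parse too
  pq <- file.path(dirp, "pose.pdbqt")
  writeLines(c("MODEL 1", "REMARK VINA RESULT:      -8.4      0.000",
               "ENDMDL", "MODEL 2",
               "REMARK VINA RESULT:      -7.9      1.222"), pq)
  expect_equal(collate_scores(c(pose = pq))$best_affinity, -8.4)
  # unparseable files are dropped with a warning, not fatal
  junk <- file.path(dirp, "junk.log")
  writeLines("nothing here", junk)
  expect_warning(tab3 <- collate_scores(c(mixed, junk = junk)),
                 "cannot parse")
  expect_equal(nrow(tab3), 2L)
})
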