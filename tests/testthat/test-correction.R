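test_that("posterior correction matches the closed-form examples", {
  # one class, 4 shifts exactly mean + 2, k = 1
  cl <- make_classified("C_ali", 58, 56, 1, n = 4)
  pc <- posterior_correction(cl, "C_ali")
  expect_equal(pc$mean_ppm, 2)
  expect_equal(pc$uncertainty_ppm, 0.5)        # 1/sqrt(n k)
  expect_true(pc$retained)                     # 2.0 >= 3 * 0.5
  # two classes: (n=2, k=4, rbar=1) and (n=2, k=1, rbar=2)
  cl2 <- rbind(make_classified("C_ali", 57, 56, 4, n = 2),
               make_classified("C_ali", 58, 56, 1, n = 2))
  pc2 <- posterior_correction(cl2, "C_ali")
  expect_equal(pc2$mean_ppm, 1.2)              # (8*1 + 2*2)/10
  expect_equal(pc2$uncertainty_ppm, 10^-0.5)
  expect_equal(pc2$total_precision, 10)
  expect_true(pc2$retained)
  # retention boundary: n=1, k=1, rbar=2 -> 2.0 < 3.0, not retained
  pc3 <- posterior_correction(make_classified("C_ali", 58, 56, 1), "C_ali")
  expect_equal(pc3$mean_ppm, 2)
  expect_equal(pc3$uncertainty_ppm, 1)
  expect_false(pc3$retained)
  expect_true(pc3$low_confidence)              # n below the floor
  # exact boundary retains (>=): |c| == 3 sigma
  pc4 <- posterior_correction(make_classified("C_ali", 59, 56, 1), "C_ali")
  expect_equal(pc4$mean_ppm, 3)
  expect_true(pc4$retained)
})

test_that("closed form agrees with numerical integration of the posterior", {
  set.seed(10)
  for (rep in 1:20) {
    n_classes <- sample(1:5, 1)
    rows <- do.call(rbind, lapply(seq_len(n_classes), function(j) {
      n <- sample(1:10, 1)
      k <- runif(1, 0.1, 5)
      make_classified("C_ali", 56 + rnorm(n, 0, 2), 56, k)
    }))
    pc <- posterior_correction(rows, "C_ali")
    or <- numeric_posterior(rows$value_ppm - rows$class_mean_ppm,
                            rows$class_precision)
    expect_equal(pc$mean_ppm, or$mean,
                 tolerance = 1e-6 * max(1, abs(or$mean)))
    expect_equal(pc$uncertainty_ppm, or$sd, tolerance = 1e-6)
  }
})

test_that("a constant offset moves the posterior mean exactly, not the error", {
  db <- tiny_refdb()
  e <- make_entry(db, n_shifts = 120, seed = 20)
  base <- group_corrections(e$classified)
  for (delta in c(-5, 0.5, 2)) {
    shifted <- e$classified
    shifted$value_ppm <- shifted$value_ppm + delta
    gc <- group_corrections(shifted)
    present <- base$n_shifts_used > 0
    expect_equal(gc$mean_ppm[present], base$mean_ppm[present] + delta,
                 tolerance = 1e-9)
    expect_identical(gc$uncertainty_ppm, base$uncertainty_ppm)
  }
})

test_that("exactly five group corrections; every classified shift in one group", {
  db <- tiny_refdb()
  e <- make_entry(db, n_shifts = 150, seed = 21)
  gc <- group_corrections(e$classified)
  expect_identical(nrow(gc), 5L)
  expect_identical(sort(gc$group), sort(c("H", "N", "C_ali", "C_aro", "C_noH")))
  expect_identical(sum(gc$n_shifts_used), nrow(e$classified))
  expect_identical(as.integer(table(e$classified$group)[gc$group]),
                   gc$n_shifts_used)
})

test_that("classification excludes unmapped residues and absent classes", {
  db <- tiny_refdb()
  e <- make_entry(db, n_shifts = 50, seed = 22)
  # drop half the residues from the mapping
  m2 <- e$mapping
  m2$pairs <- m2$pairs[1:25, ]
  cl <- classify_shifts(e$table, e$annotations, m2, db)
  expect_identical(nrow(cl), 25L)
  expect_identical(attr(cl, "excluded")$unmapped, 25L)
  # remove one class from the database -> its shifts are excluded
  db2 <- db
  drop <- db2$stats$atom_type == "CA"
  db2$stats <- db2$stats[!drop, ]
  db2$scheme$bins <- db2$scheme$bins[db2$scheme$bins$atom_type != "CA", ]
  cl2 <- classify_shifts(e$table, e$annotations, e$mapping, db2)
  n_ca <- sum(e$table$records$atom_name == "CA")
  expect_identical(attr(cl2, "excluded")$no_class, n_ca)
  expect_identical(nrow(cl2), 50L - n_ca)
  # empty intersection errors
  m0 <- e$mapping; m0$pairs <- m0$pairs[0, ]
  expect_error(classify_shifts(e$table, e$annotations, m0, db),
               "no classifiable shifts")
})

test_that("apply_corrections subtracts retained corrections only", {
  db <- tiny_refdb()
  e <- make_entry(db, n_shifts = 200, offsets = c(C_ali = 2), seed = 23)
  gc <- group_corrections(e$classified)
  expect_true(gc$retained[gc$group == "C_ali"])
  out <- apply_corrections(e$table, gc)
  rec <- out$records
  g <- assign_group(rec$residue_type, rec$atom_name)
  cali <- g == "C_ali"
  applied <- gc$mean_ppm[gc$group == "C_ali"]
  expect_equal(rec$value_ppm[cali], rec$value_ppm_original[cali] - applied)
  nr <- !gc$retained[match(g, gc$group)]
  expect_identical(rec$value_ppm[nr], rec$value_ppm_original[nr])
  # idempotence: recomputing on corrected data gives ~0 within uncertainty
  cl2 <- e$classified
  adj <- ifelse(gc$retained[match(cl2$group, gc$group)],
                gc$mean_ppm[match(cl2$group, gc$group)], 0)
  cl2$value_ppm <- cl2$value_ppm - adj
  gc2 <- group_corrections(cl2)
  i <- gc2$n_shifts_used > 0
  expect_true(all(abs(gc2$mean_ppm[i]) <= gc2$uncertainty_ppm[i] * 3))
  expect_false(any(gc2$retained))
})

test_that("Z-scores standardize corrected shifts against their class", {
  cl <- make_classified("C_ali", 56, 56, 4)
  expect_equal(zscore_shifts(cl)$z, 0)
  cl$value_ppm <- 56 + 1 / sqrt(4)
  expect_equal(zscore_shifts(cl)$z, 1)
  cl$value_ppm <- 56 + 1.5
  expect_equal(zscore_shifts(cl)$z, 3)          # k=4, residual 1.5
  # retained correction is removed before standardization
  cl4 <- make_classified("C_ali", 58, 56, 1, n = 4)
  gc <- group_corrections(cl4)
  zs <- zscore_shifts(cl4, gc)
  expect_equal(zs$corrected_ppm, rep(56, 4))
  expect_equal(zs$z, rep(0, 4))
})

test_that("stability experiment is deterministic and quiet at fraction 0", {
  db <- tiny_refdb()
  e <- make_entry(db, n_shifts = 400, seed = 24)
  gc <- group_corrections(e$classified)
  expect_false(any(gc$retained))   # zero-offset entry needs no correction
  t1 <- stability_experiment(e$classified, c(0, 0.3, 0.6), n_samples = 50,
                             seed = 99)
  t2 <- stability_experiment(e$classified, c(0, 0.3, 0.6), n_samples = 50,
                             seed = 99)
  expect_identical(t1, t2)
  expect_identical(sum(t1$n_retained[t1$fraction == 0]), 0L)
  expect_error(stability_experiment(e$classified, c(0.5, 1.0)), "fractions")
})

test_that("random scatter inflates the posterior error, in expectation", {
  db <- tiny_refdb()
  u_base <- u_noisy <- numeric(10)
  for (s in 1:10) {
    # refit the reference on data of each noise level, as the discussion
    # scenario prescribes: scatter widens class variances, hence the error
    clean <- make_observations(db, n_shifts = 600, noise_scale = 1,
                               seed = 300 + s)
    noisy <- clean
    set.seed(400 + s)
    noisy$value_ppm <- noisy$value_ppm + rnorm(nrow(noisy), 0, 2)
    db_c <- build_reference_db(clean, target_bin_count = 50, mode = "atom")
    db_n <- build_reference_db(noisy, target_bin_count = 50, mode = "atom")
    g_c <- shiftref:::corrections_for_observations(clean, db_c)
    g_n <- shiftref:::corrections_for_observations(noisy, db_n)
    u_base[s] <- g_c$uncertainty_ppm[g_c$group == "C_ali"]
    u_noisy[s] <- g_n$uncertainty_ppm[g_n$group == "C_ali"]
  }
  expect_gt(mean(u_noisy), mean(u_base))
})
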