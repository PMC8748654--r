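test_that("threshold keeps peaks strictly above the cutoff", {
  pl <- peak_list("S1", "SM", mz = 700 + 1:10, intensity = 1000 * (1:10))
  out <- threshold_peaks(pl, 3000)
  expect_equal(nrow(out$peaks), 7)
  expect_equal(min(out$peaks$intensity), 4000)
  expect_equal(threshold_peaks(pl, 0)$peaks, pl$peaks)
  # brute-force oracle on random peaks
  set.seed(3)
  pl2 <- peak_list("S1", "SM", mz = sort(runif(50, 600, 900)),
                   intensity = runif(50, 0, 10000))
  thr <- 4321
  expect_equal(threshold_peaks(pl2, thr)$peaks$intensity,
               pl2$peaks$intensity[pl2$peaks$intensity > thr])
})

test_that("mass tolerance boundary is inclusive at 5 mDa", {
  db <- make_toy_db("SM 34:1")
  mz0 <- db$exact_mz[1]
  pl <- peak_list("S1", "SM", mz = c(mz0 + 0.0049, mz0 + 0.0051),
                  intensity = c(100, 200))
  a <- match_peaks(pl, db, tolerance = 5)
  expect_equal(nrow(a), 1)
  expect_equal(a$mz, mz0 + 0.0049)
  # exact boundary matches
  pl2 <- peak_list("S1", "SM", mz = mz0 + 0.005, intensity = 10)
  expect_equal(nrow(match_peaks(pl2, db, tolerance = 5)), 1)
  # empty peak list
  expect_equal(nrow(match_peaks(peak_list("S1", "SM", numeric(0), numeric(0)),
                                db)), 0)
})

test_that("matching equals brute-force nearest-neighbour search", {
  db <- default_lipid_db()
  win <- db[db$lipid_class == "SM", ]
  set.seed(8)
  mz <- sort(c(win$exact_mz + runif(nrow(win), -0.008, 0.008),
               runif(10, 640, 830)))
  pl <- peak_list("S1", "SM", mz, runif(length(mz), 1, 1000))
  got <- match_peaks(pl, db, tolerance = 5)
  # oracle: exhaustive per-peak nearest within tolerance, then per-species
  # most intense
  tol <- 0.005
  assigned <- lapply(seq_along(pl$peaks$mz), function(i) {
    d <- abs(pl$peaks$mz[i] - win$exact_mz)
    if (min(d) > tol) return(NULL)
    best <- which(d == min(d))
    best <- best[which.min(win$exact_mz[best])]
    c(i = i, sp = best)
  })
  assigned <- do.call(rbind, assigned)
  exp_rows <- lapply(unique(assigned[, "sp"]), function(sp) {
    peaks <- assigned[assigned[, "sp"] == sp, "i"]
    peaks[which.max(pl$peaks$intensity[peaks])]
  })
  exp_names <- sort(win$name[unique(assigned[, "sp"])])
  expect_setequal(got$name, exp_names)
  expect_equal(sort(got$intensity),
               sort(pl$peaks$intensity[unlist(exp_rows)]))
})

test_that("matching is invariant under a uniform m/z shift", {
  db <- default_lipid_db()
  win <- db[db$lipid_class == "Cer", ]
  set.seed(4)
  mz <- win$exact_mz + runif(nrow(win), -0.004, 0.004)
  pl <- peak_list("S1", "Cer", mz, runif(length(mz), 10, 100))
  a <- match_peaks(pl, db)
  shift <- 0.5
  db2 <- db; db2$exact_mz <- db2$exact_mz + shift
  pl2 <- peak_list("S1", "Cer", mz + shift, pl$peaks$intensity)
  a2 <- match_peaks(pl2, db2)
  expect_equal(a$name, a2$name)
  expect_equal(a$delta_mz, a2$delta_mz, tolerance = 1e-6)
})

test_that("isotope correction: identity, round trip, and non-negativity", {
  db <- default_lipid_db()
  # species with no same-class d+1 neighbour: type II is a no-op and
  # type I divides by the monoisotopic fraction
  pl <- peak_list("S1", "LPC", db$exact_mz[db$name == "LPC 16:0"], 1000)
  a <- match_peaks(pl, db)
  ac <- isotope_correct(a, db, type1 = FALSE)
  expect_equal(ac$corrected_intensity, 1000)
  ac2 <- isotope_correct(a, db)
  expect_equal(ac2$corrected_intensity,
               1000 / monoisotopic_fraction(lipid_formula("LPC 16:0")))
  # adversarial: huge M+2 overlap floors at zero
  win <- db[db$name %in% c("SM 41:1", "SM 41:2"), ]
  pl2 <- peak_list("S1", "SM", win$exact_mz[match(c("SM 41:1", "SM 41:2"), win$name)],
                   c(10, 1e7))
  a2 <- isotope_correct(match_peaks(pl2, db), db)
  expect_gte(min(a2$corrected_intensity), 0)
  expect_equal(a2$corrected_intensity[a2$name == "SM 41:1"], 0)
  # missing formula errors with the species name
  a_bad <- a; a_bad$name <- "XX 1:1"
  expect_error(isotope_correct(a_bad, db), "XX 1:1")
})

test_that("double-bond neighbours generated with full envelopes are recovered within 1%", {
  db <- default_lipid_db()
  truth <- c(`SM 41:1` = 8, `SM 41:2` = 30)
  m <- conc_matrix(matrix(truth, 1, dimnames = list("S1", names(truth))))
  pls <- generate_peaklists(m, db, spectrum_config(
    mz_jitter_sd = 0, include_isotopes = TRUE, seed = 1))
  rec <- lipidquant_cohort(pls, db, min_intensity = 0)
  expect_equal(rec$values["S1", names(truth)], truth, tolerance = 0.01)
})

test_that("quantitation is a pure intensity ratio times the IS concentration", {
  a <- data.frame(name = c("SM 41:1", "SM 30:1"), lipid_class = "SM",
                  mz = c(801.68, 647.51), intensity = c(250, 100),
                  delta_mz = 0, corrected_intensity = c(250, 100))
  ist <- data.frame(lipid_class = "SM", is_name = "SM 30:1", concentration = 4)
  out <- quantify_peaks(a, ist)
  expect_equal(out$concentration, 2.5 * 4)
  # unit ratio
  a$corrected_intensity <- c(100, 100)
  ist$concentration <- 10
  expect_equal(quantify_peaks(a, ist)$concentration, 10)
  # absent IS -> missing with warning, not zero
  a2 <- a[a$name != "SM 30:1", ]
  expect_warning(out2 <- quantify_peaks(a2, ist), "absent or zero")
  expect_equal(nrow(out2), 0)
})

test_that("quantitation is invariant to a global intensity scale", {
  db <- default_lipid_db()
  m <- make_db_cohort(n = 2, seed = 21)
  pls_a <- generate_peaklists(m, db, spectrum_config(
    mz_jitter_sd = 0, response_factor = 1e4, seed = 7))
  pls_b <- generate_peaklists(m, db, spectrum_config(
    mz_jitter_sd = 0, response_factor = 7e4, seed = 7))
  rec_a <- lipidquant_cohort(pls_a, db, min_intensity = 0,
                             isotope_correction = FALSE)
  rec_b <- lipidquant_cohort(pls_b, db, min_intensity = 0,
                             isotope_correction = FALSE)
  expect_equal(rec_a$values, rec_b$values, tolerance = 1e-10)
})

test_that("matrix assembly: unions, permutation invariance, duplicates", {
  r1 <- data.frame(name = c("SM 41:1", "Cer 41:1"), concentration = c(1, 2))
  r2 <- data.frame(name = c("LPC 18:2"), concentration = 3)
  r3 <- data.frame(name = c("SM 41:1"), concentration = 4)
  m <- build_matrix(list(A = r1, B = r2, C = r3))
  expect_equal(dim(m), c(3L, 3L))
  expect_true(is.na(m$values["B", "SM 41:1"]))
  expect_equal(m$provenance["B", "SM 41:1"], "absent")
  m_perm <- build_matrix(list(C = r3, A = r1, B = r2))
  expect_equal(m$values[c("A", "B", "C"), ], m_perm$values[c("A", "B", "C"), ])
  expect_error(build_matrix(list(A = r1, A = r2)), "duplicate sample ids")
  single <- build_matrix(list(A = r1))
  expect_equal(nrow(single$values), 1)
})

test_that("end-to-end round trip recovers concentrations (5% clean, 15% with isotopes+noise)", {
  db <- default_lipid_db()
  endo <- db$name[!db$is_internal_standard]
  m <- make_db_cohort(n = 4, seed = 31)
  pls <- generate_peaklists(m, db, spectrum_config(mz_jitter_sd = 0, seed = 1))
  rec <- lipidquant_cohort(pls, db, min_intensity = 0,
                           isotope_correction = FALSE)
  expect_lt(max(abs(rec$values[, endo] / m$values[, endo] - 1)), 0.05)
  pls2 <- generate_peaklists(m, db, spectrum_config(
    mz_jitter_sd = 0.5, include_isotopes = TRUE, noise_floor = 800, seed = 2))
  rec2 <- lipidquant_cohort(pls2, db, min_intensity = 3000)
  common <- intersect(colnames(rec2$values), endo)
  expect_gte(length(common), length(endo) - 2)
  err <- abs(rec2$values[, common] / m$values[, common] - 1)
  expect_lt(max(err, na.rm = TRUE), 0.15)
})
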