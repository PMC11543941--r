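test_that("phantom generation is a pure function of (params, seed)", {
  ph <- fast_phantom()
  a <- simulate_bscan(ph, seed = 5)
  b <- simulate_bscan(ph, seed = 5)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$codes, b$mask$codes)
  c_ <- simulate_bscan(ph, seed = 6)
  expect_false(identical(a$mask$codes, c_$mask$codes))
})

test_that("with all lesions off only the base anatomy remains", {
  off <- lapply(c("IRF", "SRF", "SHRM", "Fibrosis", "dPED", "fPED", "ERM", "PHM"),
                function(x) list(prob = 0))
  names(off) <- c("IRF", "SRF", "SHRM", "Fibrosis", "dPED", "fPED", "ERM", "PHM")
  ph <- fast_phantom(lesions = off)
  sc <- oct_class_scheme()
  for (seed in 1:3) {
    m <- simulate_bscan(ph, seed = seed)$mask
    present <- sc$labels[sort(unique(as.vector(m$codes))) + 1]
    expect_setequal(present, c("background", "NR", "RPE", "Choroid"))
  }
})

test_that("generated anatomy respects the axial ordering constraints", {
  ph <- fast_phantom()
  sc <- oct_class_scheme()
  code <- function(l) class_code(sc, l)
  for (seed in 1:8) {
    m <- simulate_bscan(ph, seed = seed)$mask$codes
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      nr <- which(col == code("NR"))
      if (!length(nr)) next
      rpe <- which(col == code("RPE"))
      for (cl in c("ERM", "PHM")) {  # membranes above the retina
        w <- which(col == code(cl))
        if (length(w)) expect_true(max(w) < min(nr))
      }
      w <- which(col == code("IRF"))  # cysts inside the retina:
      if (length(w)) {                # below any membrane, above the RPE
        above <- which(col %in% code(c("ERM", "PHM")))
        if (length(above)) expect_true(min(w) > max(above))
        if (length(rpe)) expect_true(max(w) < min(rpe))
      }
      for (cl in c("SRF", "SHRM")) {  # subretinal: below NR, above RPE
        w <- which(col == code(cl))
        if (length(w) && length(rpe))
          expect_true(min(w) > max(nr) && max(w) < min(rpe))
      }
      for (cl in c("dPED", "fPED")) {  # sub-RPE
        w <- which(col == code(cl))
        if (length(w) && length(rpe)) expect_true(min(w) > min(rpe))
      }
      ch <- which(col == code("Choroid"))
      if (length(ch) && length(rpe)) expect_true(min(ch) > max(rpe))
    }
  }
})

test_that("a requested SRF pocket realizes close to its nominal area", {
  # degenerate size ranges pin the half-ellipse: area = pi/2 * halfwidth * height
  ph <- phantom_params(image_size = 128, lesions = list(
    SRF = list(prob = 1, height = c(0.08, 0.08), halfwidth = c(0.15, 0.15)),
    SHRM = list(prob = 0), Fibrosis = list(prob = 0),
    dPED = list(prob = 0), fPED = list(prob = 0), IRF = list(prob = 0)))
  sc <- oct_class_scheme()
  nominal <- pi / 2 * (0.15 * 128) * (0.08 * 128)
  for (seed in 1:6) {
    m <- simulate_bscan(ph, seed = seed)$mask
    got <- sum(m$codes == class_code(sc, "SRF"))
    expect_gt(got, 0.8 * nominal)
    expect_lt(got, 1.2 * nominal)
  }
})

test_that("annotator disagreement level 0 reproduces the mask exactly", {
  m <- simulate_bscan(fast_phantom(), seed = 3)$mask
  out <- simulate_annotator(m, 0, seed = 1)
  expect_identical(out$codes, m$codes)
  rep_ <- f1_per_class(list(out), list(m))
  expect_true(all(rep_$f1 == 1 | is.na(rep_$f1)))
})

test_that("fibrosis F1 degrades monotonically with the disagreement level", {
  ph <- phantom_params(image_size = 96, lesions = list(
    Fibrosis = list(prob = 1, height = c(0.08, 0.08), halfwidth = c(0.12, 0.12))))
  m <- simulate_bscan(ph, seed = 9)$mask
  sc <- oct_class_scheme()
  f1s <- sapply(0:4, function(lev) {
    pert <- simulate_annotator(m, lev, seed = 42, direction = "erode")
    rep_ <- f1_per_class(list(pert), list(m), sc)
    rep_$f1[rep_$class == "Fibrosis"]
  })
  expect_true(all(diff(f1s) <= 1e-12))
  expect_lt(f1s[5], f1s[1])
})

test_that("annotator perturbation leaves the background untouched", {
  m <- simulate_bscan(fast_phantom(), seed = 12)$mask
  for (lev in c(1, 3)) {
    pert <- simulate_annotator(m, lev, seed = 7)
    expect_identical(pert$codes == 0L, m$codes == 0L)
  }
})

test_that("a zero-variance cohort is exactly the linear predictor", {
  p <- cohort_params(n_eyes = 5, va_noise_sd = 0, va_sd = 0)
  p$sds[] <- 0
  co <- simulate_cohort(p, seed = 1)
  expect_equal(nrow(co), 15)
  expect_false(anyNA(co))
  base <- co[co$month == 0, ]
  expect_true(all(vapply(split(base$SRF, base$eye_id), length, 1L) == 1))
  # all eyes identical within each timepoint
  for (mk in cohort_markers()) for (m in c(0, 3, 12))
    expect_length(unique(co[[mk]][co$month == m]), 1)
  x <- unlist(base[1, cohort_markers()])
  x[["CRT"]] <- x[["CRT"]] / 1000
  eta <- p$va_coef[["intercept"]] + sum(p$va_coef[cohort_markers()] * x)
  expect_equal(unique(co$va_logmar[co$month == 12]), eta, tolerance = 1e-12)
})

test_that("cohort marginals recover the truncated-normal moments at n = 10^4", {
  p <- cohort_params(n_eyes = 10000)
  co <- simulate_cohort(p, seed = 99)
  for (mk in c("SRF", "IRF", "fPED", "CRT")) {
    for (m in c(0, 3)) {
      j <- match(paste0("m", m), colnames(p$means))
      mom <- cohort_moments(p$means[mk, j], p$sds[mk, j])
      v <- co[[mk]][co$month == m]
      se <- mom$sd / sqrt(length(v))
      expect_lt(abs(mean(v) - mom$mean), 3 * se + 1e-9)
    }
  }
  # baseline SRF mean: nominal (pre-truncation) parameter is 0.08; the
  # realized mean exceeds it because volumes are truncated at zero
  expect_gt(mean(co$SRF[co$month == 0]), 0.08)
})

test_that("regression on a large simulated cohort recovers the IRF coefficient sign", {
  co <- simulate_cohort(cohort_params(n_eyes = 5000), seed = 7)
  fit <- fit_va_regression(co)
  irf <- fit$coefficients[fit$coefficients$term == "IRF", ]
  expect_gt(irf$b, 0)        # more intraretinal fluid -> worse logMAR
  expect_lt(irf$p, 0.05)
})

test_that("degenerate cohorts are rejected", {
  expect_error(cohort_params(n_eyes = 1), "n_eyes")
})
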