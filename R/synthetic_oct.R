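# Synthetic layered OCT phantoms, annotator perturbations, cohort tables.
#
# The generator is the package's stand-in for an annotated patient scan set:
# it builds layered B-scans whose ground-truth masks are exact by
# construction, so segmentation, ensembling, evaluation and quantification
# can all be exercised and scored without external data.

#' Parameters for the synthetic B-scan phantom generator
#'
#' Geometry is parameterised as smooth 1-D boundary curves (retina top,
#' Bruch's membrane, choroid base) plus a lesion menu. Lesion sizes are
#' fractions of the image height/width so phantoms scale with `image_size`.
#' Heights/half-widths refer to half-ellipse lesion profiles; membranes
#' (ERM/PHM) are thin 1-2 px curves. Per-class intensity means are on a
#' [0, 1] reflectivity scale, loosely ordered like real tissue (fluid dark,
#' fibrosis/RPE bright) but kept well separated; additive Gaussian noise.
#'
#' @param image_size Side length in pixels (square B-scan; >= 32).
#' @param lesions Named list overriding entries of the default lesion menu
#'   (per class: `prob` presence probability and size ranges).
#' @param intensity_means Named numeric vector overriding per-class mean
#'   reflectivity (names = scheme labels incl. background).
#' @param noise_sd Additive Gaussian intensity noise SD.
#' @param seed Integer seed; fully determines the phantom.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 256, lesions = list(),
                           intensity_means = NULL, noise_sd = 0.03,
                           seed = NULL) {
  .check(image_size >= 32, "image_size %d too small to host the layer geometry (min 32)",
         image_size)
  menu <- list(
    IRF  = list(prob = 0.7, n_max = 3, rx = c(0.03, 0.08), ry = c(0.02, 0.05)),
    SRF  = list(prob = 0.7, height = c(0.04, 0.10), halfwidth = c(0.08, 0.20)),
    SHRM = list(prob = 0.5, height = c(0.03, 0.07), halfwidth = c(0.05, 0.12)),
    Fibrosis = list(prob = 0.5, height = c(0.03, 0.08), halfwidth = c(0.05, 0.12)),
    dPED = list(prob = 0.5, height = c(0.04, 0.10), halfwidth = c(0.08, 0.15)),
    fPED = list(prob = 0.6, height = c(0.05, 0.12), halfwidth = c(0.08, 0.18)),
    ERM  = list(prob = 0.5, halfwidth = c(0.15, 0.40)),
    PHM  = list(prob = 0.5, offset = c(0.04, 0.10))
  )
  for (nm in names(lesions)) {
    .check(nm %in% names(menu), "unknown lesion class '%s'", nm)
    menu[[nm]] <- utils::modifyList(menu[[nm]], lesions[[nm]])
  }
  for (nm in names(menu))
    .check(menu[[nm]]$prob >= 0 && menu[[nm]]$prob <= 1,
           "presence probability for %s must be in [0,1]", nm)
  means <- c(background = 0.03, ERM = 0.80, NR = 0.45, RPE = 0.88,
             IRF = 0.10, SRF = 0.18, SHRM = 0.68, dPED = 0.55, fPED = 0.62,
             Fibrosis = 0.95, Choroid = 0.30, PHM = 0.25)
  if (!is.null(intensity_means)) means[names(intensity_means)] <- intensity_means
  structure(list(image_size = as.integer(image_size), lesions = menu,
                 intensity_means = means, noise_sd = noise_sd, seed = seed),
            class = "phantom_params")
}

# smooth 1-D boundary curve over columns 1..W (returned in row units)
.smooth_curve <- function(W, base, amp) {
  x <- seq_len(W) / W
  base + amp * sin(2 * pi * (stats::runif(1, 0.5, 2)) * x + stats::runif(1, 0, 2 * pi)) +
    amp * 0.5 * (x - 0.5) * stats::runif(1, -1, 1)
}

# sample a lateral support [centre - hw, centre + hw] disjoint from `taken`
.sample_support <- function(W, hw_range, taken) {
  for (try in 1:25) {
    hw <- stats::runif(1, hw_range[1], hw_range[2]) * W
    if (0.12 * W + hw >= 0.88 * W - hw) next  # too wide for the canvas
    xc <- stats::runif(1, 0.12 * W + hw, 0.88 * W - hw)
    iv <- c(xc - hw, xc + hw)
    ok <- all(vapply(taken, function(t) iv[2] < t[1] || iv[1] > t[2], logical(1)))
    if (ok) return(list(xc = xc, hw = hw))
  }
  NULL  # no room left; lesion silently skipped
}

# half-ellipse height profile over columns
.bump_profile <- function(W, xc, hw, h) {
  x <- seq_len(W)
  u <- (x - xc) / hw
  p <- numeric(W)
  in_s <- abs(u) < 1
  p[in_s] <- h * sqrt(1 - u[in_s]^2)
  p
}

#' Simulate a synthetic OCT B-scan with its exact ground-truth mask
#'
#' Builds the layered anatomy top-down: vitreous (background), optional
#' posterior hyaloid and epiretinal membranes, neurosensory retina with
#' optional intraretinal cysts, a subretinal space holding SRF pockets,
#' SHRM deposits or fibrosis patches, the RPE band elevated by optional
#' drusenoid/fibrovascular PED domes, choroid, and background below. The
#' mask is exact by construction; the image draws each pixel's intensity
#' from its class mean plus Gaussian noise.
#'
#' @param params A `phantom_params`.
#' @param seed Integer seed (default `params$seed`). The pair
#'   (`params`, `seed`) fully determines the output.
#' @param scheme An `oct_scheme` (default [oct_class_scheme()]).
#' @return `list(image = <bscan_image>, mask = <label_mask>)`.
#' @export
simulate_bscan <- function(params = phantom_params(), seed = params$seed,
                           scheme = oct_class_scheme()) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(seed, {
    H <- params$image_size; W <- H
    code <- function(l) unname(scheme$codes[l])
    les <- params$lesions

    y_top <- .smooth_curve(W, H * stats::runif(1, 0.26, 0.34), H * 0.03)
    y_br  <- y_top + .smooth_curve(W, H * stats::runif(1, 0.20, 0.26), H * 0.02)
    t_rpe <- max(2L, round(H * 0.012))
    chor  <- .smooth_curve(W, H * stats::runif(1, 0.14, 0.18), H * 0.02)

    present <- vapply(les, function(l) stats::runif(1) < l$prob, logical(1))

    # PED domes elevate the RPE above Bruch's membrane
    elev <- stats::setNames(vector("list", 2), c("dPED", "fPED"))
    taken_ped <- list()
    for (cl in c("dPED", "fPED")) {
      elev[[cl]] <- numeric(W)
      if (present[[cl]]) {
        s <- .sample_support(W, les[[cl]]$halfwidth, taken_ped)
        if (!is.null(s)) {
          h <- stats::runif(1, les[[cl]]$height[1], les[[cl]]$height[2]) * H
          elev[[cl]] <- .bump_profile(W, s$xc, s$hw, h)
          taken_ped <- c(taken_ped, list(c(s$xc - s$hw, s$xc + s$hw)))
        }
      }
    }
    rpe_top <- y_br - elev$dPED - elev$fPED

    # subretinal space between NR and RPE: SRF / SHRM / fibrosis
    gap <- stats::setNames(vector("list", 3), c("SRF", "SHRM", "Fibrosis"))
    taken_sub <- list()
    for (cl in c("SRF", "SHRM", "Fibrosis")) {
      gap[[cl]] <- numeric(W)
      if (present[[cl]]) {
        s <- .sample_support(W, les[[cl]]$halfwidth, taken_sub)
        if (!is.null(s)) {
          h <- stats::runif(1, les[[cl]]$height[1], les[[cl]]$height[2]) * H
          gap[[cl]] <- .bump_profile(W, s$xc, s$hw, h)
          taken_sub <- c(taken_sub, list(c(s$xc - s$hw, s$xc + s$hw)))
        }
      }
    }
    gap_tot <- gap$SRF + gap$SHRM + gap$Fibrosis
    # keep a minimum retinal thickness above the subretinal space
    max_gap <- pmax(rpe_top - y_top - H * 0.06, 0)
    scl <- ifelse(gap_tot > max_gap & gap_tot > 0, max_gap / gap_tot, 1)
    for (cl in names(gap)) gap[[cl]] <- gap[[cl]] * scl
    gap_tot <- gap_tot * scl
    nr_bot <- rpe_top - gap_tot

    Rm <- matrix(seq_len(H), H, W)
    bycol <- function(v) matrix(v, H, W, byrow = TRUE)
    codes <- matrix(code("background"), H, W)
    codes[Rm > bycol(y_top) & Rm <= bycol(nr_bot)] <- code("NR")
    for (cl in c("SRF", "SHRM", "Fibrosis")) {
      act <- gap[[cl]] > 0.5
      sel <- Rm > bycol(nr_bot) & Rm <= bycol(rpe_top) & bycol(act)
      codes[sel] <- code(cl)
    }
    codes[Rm > bycol(rpe_top) & Rm <= bycol(rpe_top + t_rpe)] <- code("RPE")
    for (cl in c("dPED", "fPED")) {
      act <- elev[[cl]] > 0.5
      sel <- Rm > bycol(rpe_top + t_rpe) & Rm <= bycol(y_br + t_rpe) & bycol(act)
      codes[sel] <- code(cl)
    }
    codes[Rm > bycol(y_br + t_rpe) & Rm <= bycol(y_br + t_rpe + chor)] <- code("Choroid")

    # intraretinal cysts, strictly inside the NR band
    if (present[["IRF"]]) {
      n_cyst <- sample.int(les$IRF$n_max, 1)
      for (k in seq_len(n_cyst)) {
        xc <- stats::runif(1, 0.15 * W, 0.85 * W)
        jc <- pmin(pmax(round(xc), 1), W)
        lo <- y_top[jc] + H * 0.02; hi <- nr_bot[jc] - H * 0.02
        if (hi <= lo) next
        yc <- stats::runif(1, lo, hi)
        rx <- stats::runif(1, les$IRF$rx[1], les$IRF$rx[2]) * W
        ry <- stats::runif(1, les$IRF$ry[1], les$IRF$ry[2]) * H
        Cm <- matrix(seq_len(W), H, W, byrow = TRUE)
        inside <- ((Cm - xc) / rx)^2 + ((Rm - yc) / ry)^2 <= 1
        codes[inside & codes == code("NR")] <- code("IRF")
      }
    }

    th_mem <- max(1L, round(H * 0.008))
    if (present[["ERM"]]) {
      s <- .sample_support(W, les$ERM$halfwidth, list())
      if (!is.null(s)) {
        act <- abs(seq_len(W) - s$xc) < s$hw
        sel <- Rm > bycol(y_top - th_mem) & Rm <= bycol(y_top) & bycol(act)
        codes[sel & codes == code("background")] <- code("ERM")
      }
    }
    if (present[["PHM"]]) {
      d <- stats::runif(1, les$PHM$offset[1], les$PHM$offset[2]) * H +
        .smooth_curve(W, 0, H * 0.01)
      sel <- Rm > bycol(y_top - d - th_mem) & Rm <= bycol(y_top - d)
      codes[sel & codes == code("background")] <- code("PHM")
    }

    mu <- params$intensity_means[scheme$labels[codes + 1L]]
    img <- matrix(mu, H, W) + stats::rnorm(H * W, 0, params$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    list(image = bscan_image(img, axial_um_per_px = 1900 / H,
                             lateral_um_per_px = 6000 / W),
         mask = label_mask(codes, scheme))
  })
}

# fill NA pixels from the nearest labelled pixel in the same column
# (above first, then below); layered anatomy makes vertical fill natural
.fill_na_vertical <- function(m) {
  for (it in seq_len(2 * nrow(m))) {
    if (!anyNA(m)) break
    na <- is.na(m)
    above <- rbind(NA, m[-nrow(m), , drop = FALSE])
    take <- na & !is.na(above)
    m[take] <- above[take]
    na <- is.na(m)
    if (any(na)) {
      below <- rbind(m[-1, , drop = FALSE], NA)
      take <- na & !is.na(below)
      m[take] <- below[take]
    }
  }
  m[is.na(m)] <- 0L
  m
}

#' Simulate an imperfect human annotator
#'
#' Perturbs a ground-truth mask with boundary-localised disagreement:
#' each targeted class region is morphologically dilated or eroded by a
#' disc of radius `disagreement_level` pixels. Dilation only claims other
#' foreground pixels (background topology is preserved); pixels freed by
#' erosion inherit the nearest remaining label in their column. Level 0
#' returns the mask unchanged; expected F1 against the input is
#' non-increasing in the level.
#'
#' @param mask A `label_mask` (the consensus / ground truth).
#' @param disagreement_level Non-negative perturbation radius in pixels.
#' @param seed Integer seed for the direction/order draws; a fixed seed with
#'   increasing level gives nested, monotonically growing perturbations.
#' @param classes Ambiguous classes to perturb (default: the hard-to-annotate
#'   lesions SHRM, fPED, dPED, Fibrosis).
#' @param direction Optional: "dilate", "erode", or a named vector per class;
#'   default draws one direction per class at random.
#' @return A perturbed `label_mask`.
#' @export
simulate_annotator <- function(mask, disagreement_level, seed = NULL,
                               classes = c("SHRM", "fPED", "dPED", "Fibrosis"),
                               direction = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  .check(disagreement_level >= 0, "disagreement_level must be >= 0")
  r <- as.integer(round(disagreement_level))
  scheme <- mask$scheme
  with_seed(seed, {
    codes <- mask$codes
    present <- classes[class_code(scheme, classes) %in% unique(as.vector(codes))]
    if (length(present) == 0) return(label_mask(codes, scheme))
    ord <- sample(present)
    dirs <- stats::setNames(sample(c("dilate", "erode"), length(ord), replace = TRUE), ord)
    if (!is.null(direction)) {
      if (is.null(names(direction))) dirs[] <- direction
      else dirs[names(direction)] <- direction
    }
    if (r == 0) return(label_mask(codes, scheme))
    brush <- EBImage::makeBrush(2L * r + 1L, "disc")
    for (cl in ord) {
      cc <- class_code(scheme, cl)
      reg <- codes == cc
      if (!any(reg)) next
      if (dirs[[cl]] == "dilate") {
        grown <- EBImage::dilate(reg * 1, brush) > 0.5
        codes[grown & codes != 0L] <- cc
      } else {
        kept <- EBImage::erode(reg * 1, brush) > 0.5
        codes[reg & !kept] <- NA_integer_
        codes <- .fill_na_vertical(codes)
      }
    }
    label_mask(codes, scheme)
  })
}

#' Parameters for the synthetic longitudinal cohort generator
#'
#' Defaults reproduce the study conditions of a treatment-naive nAMD cohort
#' under anti-VEGF therapy: per-marker volume means/SDs at months 0, 3 and
#' 12 (volumes in the source's abstract volume units, central retinal
#' thickness CRT in micrometres), and a linear model for 12-month visual
#' acuity (logMAR) on the baseline markers. Volumes are drawn from normals
#' truncated at zero (several SDs exceed their means); truncation shifts the
#' realized means upward, which [cohort_moments()] reports exactly.
#'
#' @param n_eyes Number of eyes (>= 2).
#' @param means,sds 11 x 3 numeric matrices (markers x months 0/3/12);
#'   defaults are the published cohort values.
#' @param va_coef Named coefficients of the month-12 VA model (intercept +
#'   one per baseline marker; the CRT coefficient applies per millimetre).
#' @param va_noise_sd Residual SD of the month-12 VA model.
#' @param va_mean0,va_mean3,va_sd Marginal VA (logMAR) at months 0 and 3.
#' @param seed Integer seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_eyes = 378,
                          means = NULL, sds = NULL, va_coef = NULL,
                          va_noise_sd = 0.42,
                          va_mean0 = 0.59, va_mean3 = 0.50, va_sd = 0.42,
                          seed = NULL) {
  .check(n_eyes >= 2, "n_eyes must be >= 2")
  mk <- cohort_markers()
  if (is.null(means)) {
    means <- matrix(c(
      0.01, 0.01, 0.01,     # ERM
      0.03, 0.01, 0.01,     # IRF
      0.08, 0.01, 0.01,     # SRF
      0.02, 0.01, 0.00,     # SHRM
      0.19, 0.19, 0.18,     # RPE
      0.12, 0.09, 0.09,     # fPED
      0.01, 0.01, 0.01,     # dPED
      0.02, 0.02, 0.02,     # PHM
      0.93, 0.96, 0.95,     # Choroid
      0.02, 0.02, 0.03,     # Fibrosis
      223.82, 169.65, 172.62  # CRT (µm)
    ), nrow = 11, byrow = TRUE, dimnames = list(mk, c("m0", "m3", "m12")))
  }
  if (is.null(sds)) {
    sds <- matrix(c(
      0.02, 0.02, 0.02,
      0.08, 0.07, 0.04,
      0.25, 0.09, 0.04,
      0.05, 0.02, 0.01,
      0.02, 0.02, 0.02,
      0.18, 0.15, 0.15,
      0.01, 0.01, 0.01,
      0.03, 0.03, 0.03,
      0.41, 0.41, 0.41,
      0.06, 0.06, 0.08,
      88.29, 64.11, 63.76
    ), nrow = 11, byrow = TRUE, dimnames = list(mk, c("m0", "m3", "m12")))
  }
  if (is.null(va_coef)) {
    va_coef <- c(intercept = 0.64, ERM = 2.5, IRF = 1.24, SRF = -0.15,
                 SHRM = 0.64, RPE = -1.58, fPED = 0.37, dPED = -1.19,
                 PHM = -0.36, Choroid = 0.02, Fibrosis = 1.03, CRT = 0.17)
  }
  .check(all(sds >= 0), "SDs must be non-negative")
  .check(all(rownames(means) == mk) && all(rownames(sds) == mk),
         "means/sds rows must be the 11 cohort markers in canonical order")
  .check(all(c("intercept", mk) %in% names(va_coef)),
         "va_coef must name the intercept and all 11 markers")
  structure(list(n_eyes = as.integer(n_eyes), means = means, sds = sds,
                 va_coef = va_coef, va_noise_sd = va_noise_sd,
                 va_mean0 = va_mean0, va_mean3 = va_mean3, va_sd = va_sd,
                 seed = seed),
            class = "cohort_params")
}

#' Canonical cohort marker names
#'
#' The 10 volumetric biomarkers plus central retinal thickness (CRT), in the
#' column order used throughout the cohort tables.
#' @return Character vector of length 11.
#' @export
cohort_markers <- function() {
  c("ERM", "IRF", "SRF", "SHRM", "RPE", "fPED", "dPED", "PHM",
    "Choroid", "Fibrosis", "CRT")
}

#' Realized moments of a zero-truncated normal
#'
#' Mean and SD actually realized when drawing from `N(mean, sd)` truncated
#' at zero; used to compare simulated cohort marginals against their exact
#' expectations rather than the nominal (pre-truncation) parameters.
#'
#' @param mean,sd Nominal parameters (vectorized).
#' @return `list(mean = ..., sd = ...)` of realized moments.
#' @export
cohort_moments <- function(mean, sd) {
  out_m <- ifelse(sd <= 0, pmax(mean, 0), NA_real_)
  out_s <- ifelse(sd <= 0, 0, NA_real_)
  i <- sd > 0
  if (any(i)) {
    a <- (0 - mean[i]) / sd[i]
    lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
    m <- mean[i] + sd[i] * lam
    v <- sd[i]^2 * (1 + a * lam - lam^2)
    out_m[i] <- m
    out_s[i] <- sqrt(pmax(v, 0))
  }
  list(mean = out_m, sd = out_s)
}

#' Simulate a longitudinal cohort table
#'
#' Draws per-eye marker values independently per timepoint from
#' zero-truncated normals at the configured means/SDs, and visual acuity as:
#' months 0 and 3 from their marginal normals, month 12 from the linear
#' model `VA12 = intercept + sum(coef * baseline marker) + noise` with the
#' CRT term entered per millimetre.
#'
#' @param params A `cohort_params`.
#' @param seed Integer seed (default `params$seed`).
#' @return A `data.frame` with columns `eye_id`, `month` (0/3/12),
#'   `va_logmar` and one column per marker; one row per eye-month, no
#'   missing values.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(seed, {
    n <- params$n_eyes
    mk <- cohort_markers()
    months <- c(0L, 3L, 12L)
    vols <- lapply(seq_along(months), function(j) {
      v <- vapply(mk, function(m)
        .rtnorm0(n, params$means[m, j], params$sds[m, j]), numeric(n))
      colnames(v) <- mk
      v
    })
    va0 <- stats::rnorm(n, params$va_mean0, params$va_sd)
    va3 <- stats::rnorm(n, params$va_mean3, params$va_sd)
    base <- vols[[1]]
    xb <- base
    xb[, "CRT"] <- xb[, "CRT"] / 1000  # CRT coefficient is per mm
    eta <- params$va_coef[["intercept"]] +
      as.vector(xb %*% params$va_coef[mk])
    va12 <- eta + stats::rnorm(n, 0, params$va_noise_sd)
    eye <- sprintf("E%04d", seq_len(n))
    out <- data.frame(
      eye_id = rep(eye, times = 3),
      month = rep(months, each = n),
      va_logmar = c(va0, va3, va12),
      do.call(rbind, vols),
      row.names = NULL, check.names = FALSE
    )
    out
  })
}
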