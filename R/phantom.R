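# Synthetic volumetric phantoms with graded lesion signatures.
#
# Each phantom emulates a single-sequence pelvic MR stack: ~24 slices of which
# a central contiguous run contains the gland and a sub-run carries lesion
# signal whose mean intensity and stripe texture encode the grade. The grade
# label distribution and the biopsy/surgery discordance rates mirror a
# two-hospital prostatectomy cohort.

#' Specification of a synthetic phantom cohort
#'
#' Defines the study conditions under which phantom volumes are simulated:
#' slice-count distributions, class priors for the five grade groups, lesion
#' signal strength and the confusion kernel that turns the true
#' (prostatectomy, `gg_rp`) grade into a noisy biopsy (`gg_nb`) grade.
#'
#' Slice counts are drawn so the median stack has 24 slices (range 18-24),
#' the median gland run 9 slices (range 8-12) and the median lesion run 5
#' slices (range 4-10), matching routine T2-weighted fat-suppressed pelvic
#' acquisitions. The default grade priors are the pooled five-category
#' prostatectomy marginals of a 575-patient cohort,
#' (82, 152, 117, 85, 139)/575.
#'
#' The default biopsy confusion kernel puts probability
#' (0.10, 0.30, 0.45, 0.10, 0.05) on `gg_nb - gg_rp` = (-2, -1, 0, +1, +2),
#' i.e. ~40% upgrading mass and ~15% downgrading mass before boundary
#' clipping, the discordance level reported for systematic needle biopsy.
#'
#' @param n_patients number of patients to simulate.
#' @param slices_per_patient integer range `c(min, max)` of stack sizes.
#' @param gland_slices integer range of gland-run lengths.
#' @param lesion_slices integer range of lesion-run lengths; always capped at
#'   the drawn gland-run length.
#' @param grade_probs prior over grade groups 1..5; must sum to 1.
#' @param image_size in-plane size in pixels (square slices).
#' @param signal_separation dimensionless effect size scaling both the
#'   grade-dependent lesion mean shift and the stripe-texture amplitude;
#'   0 makes all grades indistinguishable, 2 makes them easy.
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @param nb_kernel length-5 probability vector over grade shifts -2..+2
#'   applied to `gg_rp` to obtain `gg_nb` (clipped to 1..5).
#' @param second_lesion_prob probability of adding a minor second lesion run
#'   at a different grade elsewhere in the gland.
#' @param seed master RNG seed for the cohort.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_patient()], [generate_cohort()], [simulate.phantom_spec()]
#' @export
#' @examples
#' spec <- phantom_spec(n_patients = 4, seed = 1)
#' cohort <- generate_cohort(spec)
#' cohort$manifest
phantom_spec <- function(n_patients,
                         slices_per_patient = c(18L, 24L),
                         gland_slices = c(8L, 12L),
                         lesion_slices = c(4L, 10L),
                         grade_probs = c(82, 152, 117, 85, 139) / 575,
                         image_size = 256L,
                         signal_separation = 1,
                         noise_sd = 0.05,
                         nb_kernel = c(0.10, 0.30, 0.45, 0.10, 0.05),
                         second_lesion_prob = 0,
                         seed = 1L) {
  stop_if_not(is.numeric(n_patients) && n_patients >= 1,
              "n_patients must be >= 1")
  stop_if_not(length(grade_probs) == 5 && all(grade_probs >= 0) &&
                abs(sum(grade_probs) - 1) < 1e-9,
              "grade_probs must be a 5-vector summing to 1 (within 1e-9)")
  for (r in list(slices_per_patient, gland_slices, lesion_slices)) {
    stop_if_not(length(r) == 2 && all(r >= 1) && r[1] <= r[2],
                "ranges must be positive c(min, max) pairs")
  }
  stop_if_not(lesion_slices[1] >= 1 && lesion_slices[2] <= gland_slices[2],
              "lesion_slices range must lie within the gland_slices range")
  stop_if_not(gland_slices[2] <= slices_per_patient[2],
              "gland_slices range must lie within slices_per_patient")
  stop_if_not(length(nb_kernel) == 5 && all(nb_kernel >= 0) &&
                abs(sum(nb_kernel) - 1) < 1e-9,
              "nb_kernel must be a 5-vector of probabilities summing to 1")
  stop_if_not(signal_separation >= 0, "signal_separation must be >= 0")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(
    n_patients = as.integer(n_patients),
    slices_per_patient = as.integer(slices_per_patient),
    gland_slices = as.integer(gland_slices),
    lesion_slices = as.integer(lesion_slices),
    grade_probs = grade_probs,
    image_size = as.integer(image_size),
    signal_separation = signal_separation,
    noise_sd = noise_sd,
    nb_kernel = nb_kernel,
    second_lesion_prob = second_lesion_prob,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom cohort specification\n")
  cat(sprintf("  patients: %d   image: %dx%d px\n",
              x$n_patients, x$image_size, x$image_size))
  cat(sprintf("  slices/patient: %d-%d, gland run: %d-%d, lesion run: %d-%d\n",
              x$slices_per_patient[1], x$slices_per_patient[2],
              x$gland_slices[1], x$gland_slices[2],
              x$lesion_slices[1], x$lesion_slices[2]))
  cat(sprintf("  grade priors: %s\n",
              paste(sprintf("%.3f", x$grade_probs), collapse = " ")))
  cat(sprintf("  signal separation: %g   noise sd: %g   seed: %d\n",
              x$signal_separation, x$noise_sd, x$seed))
  invisible(x)
}

# Count distributions chosen so the drawn medians reproduce the reported
# slice statistics: median 24 of 18-24, median 9 of 8-12, median 5 of 4-10.
.draw_n_slices <- function(range) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1) return(vals)
  if (identical(as.integer(range), c(18L, 24L))) {
    probs <- c(rep(0.075, 6), 0.55)
  } else {
    probs <- rep(1 / length(vals), length(vals))
  }
  sample(vals, 1, prob = probs[seq_along(vals)])
}

.draw_gland_count <- function(range) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1) return(vals)
  probs <- if (identical(as.integer(range), c(8L, 12L))) {
    c(0.30, 0.30, 0.20, 0.10, 0.10)
  } else rep(1 / length(vals), length(vals))
  sample(vals, 1, prob = probs[seq_along(vals)])
}

.draw_lesion_count <- function(range, gland_n) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1) return(min(vals, gland_n))
  probs <- if (identical(as.integer(range), c(4L, 10L))) {
    c(0.30, 0.30, 0.15, 0.10, 0.07, 0.05, 0.03)
  } else rep(1 / length(vals), length(vals))
  min(sample(vals, 1, prob = probs[seq_along(vals)]), gland_n)
}

# Low-frequency random background field: coarse Gaussian grid upsampled
# bilinearly to the slice size.
.smooth_field <- function(size, amp) {
  coarse <- matrix(stats::rnorm(64), 8, 8)
  amp * as.matrix(EBImage::resize(coarse, w = size, h = size))
}

.ellipse_mask <- function(size, cx, cy, rx, ry) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

# patient-level grade labels for a cohort, drawn from the class priors
.draw_grades <- function(spec) {
  with_seed(spec$seed,
            sample(1:5, spec$n_patients, replace = TRUE,
                   prob = spec$grade_probs))
}

.perturb_grade <- function(grade, kernel) {
  delta <- sample(-2:2, 1, prob = kernel)
  min(5L, max(1L, grade + delta))
}

#' Simulate one graded phantom volume
#'
#' Draws a stack of 2D slices in which a centrally placed contiguous gland run
#' contains a contiguous lesion run. Lesion pixels carry a mean intensity
#' shift `0.06 * signal_separation * grade` plus a sinusoidal stripe texture
#' whose wavelength shortens with grade, both on top of patient- and
#' slice-level intensity offsets, a low-frequency background field and white
#' pixel noise. Non-gland slices contain background texture only. A simulated
#' biopsy grade `gg_nb` is produced by perturbing `grade` with the
#' cohort specification's confusion kernel.
#'
#' @param spec a [phantom_spec()].
#' @param grade true patient-level grade group, integer in 1..5.
#' @param seed integer seed for this volume.
#' @param patient_id identifier stored in the result.
#' @return an object of class `volume_stack` with fields `patient_id`,
#'   `slices` (list of matrices), `tumor_flags` (logical), `gg_rp`, `gg_nb`,
#'   `lesion_masks` (list, `NULL` off lesion slices) and `slice_order`.
#' @export
generate_patient <- function(spec, grade, seed = spec$seed,
                             patient_id = sprintf("P%04d", seed %% 10000L)) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  stop_if_not(length(grade) == 1 && !is.na(grade) && grade %in% 1:5,
              "grade must be a single integer in 1..5, got %s",
              paste(grade, collapse = ","))
  grade <- as.integer(grade)
  with_seed(seed, {
    size <- spec$image_size
    n <- .draw_n_slices(spec$slices_per_patient)
    g <- min(.draw_gland_count(spec$gland_slices), n)
    l <- .draw_lesion_count(spec$lesion_slices, g)

    # gland run centered in the stack (+/- 1 slice), lesion run centered in
    # the gland (+/- 1): the prostate sits mid-stack in routine acquisitions.
    gc <- floor(n / 2) + sample(-1:1, 1)                    # 0-based
    g_start <- max(0L, min(n - g, gc - floor(g / 2)))
    g_idx <- g_start + 0:(g - 1)
    lc <- min(max(gc + sample(-1:1, 1), g_start + floor(l / 2)),
              g_start + g - 1 - floor((l - 1) / 2))
    l_start <- max(g_start, min(g_start + g - l, lc - floor(l / 2)))
    l_idx <- l_start + 0:(l - 1)

    sep <- spec$signal_separation
    patient_offset <- stats::rnorm(1, 0, 0.05)
    gland_cx <- size / 2 + stats::rnorm(1, 0, 0.03 * size)
    gland_cy <- size / 2 + stats::rnorm(1, 0, 0.03 * size)
    R <- 0.28 * size
    lesion_off <- stats::runif(2, -0.3, 0.3) * R
    theta <- stats::runif(1, 0, 2 * pi)
    phase <- stats::runif(1, 0, 2 * pi)
    wavelength <- (40 - 5 * (grade - 1)) * size / 256

    # optional minor second lesion at a different grade
    second <- stats::runif(1) < spec$second_lesion_prob
    l2_idx <- integer(0); grade2 <- NA_integer_
    if (second) {
      grade2 <- sample(setdiff(1:5, grade), 1)
      # candidate slices: in the gland, separated from the main run by at
      # least one slice, and with enough gland radius to hold a lesion
      rad_of <- function(k0) R * sqrt(pmax(0, 1 - ((k0 - gc) / (g / 2 + 0.5))^2))
      free <- setdiff(g_idx, c(l_idx, min(l_idx) - 1L, max(l_idx) + 1L))
      free <- free[rad_of(free) >= 2]
      runs <- split(free, cumsum(c(1, diff(free) != 1)))
      runs <- runs[lengths(runs) >= 2]
      if (length(runs)) {
        # the run reaching closest to the gland center
        r <- runs[[which.min(vapply(runs, function(x) min(abs(x - gc)), 0))]]
        r <- r[order(abs(r - gc))]
        l2_idx <- sort(r[seq_len(min(3, length(r)))])
        # keep it contiguous
        l2_idx <- l2_idx[seq_len(which.max(c(diff(l2_idx) != 1, TRUE)))]
      } else second <- FALSE
    }
    wavelength2 <- if (second) (40 - 5 * (grade2 - 1)) * size / 256 else NA

    xg <- matrix(seq_len(size), size, size)
    yg <- matrix(seq_len(size), size, size, byrow = TRUE)
    stripe_of <- function(wl) {
      sin(2 * pi * (xg * cos(theta) + yg * sin(theta)) / wl + phase)
    }
    stripes <- stripe_of(wavelength)
    stripes2 <- if (second) stripe_of(wavelength2) else NULL

    slices <- vector("list", n)
    masks <- vector("list", n)
    flags <- logical(n)
    for (k0 in 0:(n - 1)) {
      img <- 0.30 + patient_offset + stats::rnorm(1, 0, 0.02) +
        .smooth_field(size, 0.04) +
        matrix(stats::rnorm(size * size, 0, spec$noise_sd), size, size)
      if (k0 %in% g_idx) {
        rel <- (k0 - gc) / (g / 2 + 0.5)
        rad <- R * sqrt(max(0, 1 - rel^2))
        if (rad >= 2) {
          gmask <- .ellipse_mask(size, gland_cx, gland_cy, rad, 0.8 * rad)
          img[gmask] <- img[gmask] + 0.25
          add_lesion <- function(img, gr, str, record_mask = FALSE) {
            lrad <- max(4, 0.45 * rad)
            lmask <- .ellipse_mask(size, gland_cx + lesion_off[1],
                                   gland_cy + lesion_off[2],
                                   lrad, 0.8 * lrad) & gmask
            img[lmask] <- img[lmask] + 0.06 * sep * gr +
              0.05 * sep * str[lmask]
            list(img = img, mask = lmask)
          }
          if (k0 %in% l_idx) {
            res <- add_lesion(img, grade, stripes)
            img <- res$img; masks[[k0 + 1]] <- res$mask; flags[k0 + 1] <- TRUE
          } else if (k0 %in% l2_idx) {
            res <- add_lesion(img, grade2, stripes2)
            img <- res$img; masks[[k0 + 1]] <- res$mask; flags[k0 + 1] <- TRUE
          }
        }
      }
      slices[[k0 + 1]] <- img
    }
    gg_nb <- .perturb_grade(grade, spec$nb_kernel)
    structure(list(
      patient_id = patient_id,
      slices = slices,
      tumor_flags = flags,
      gg_rp = grade,
      gg_nb = gg_nb,
      lesion_masks = masks,
      minor_grade = grade2,
      slice_order = "inferior-superior",
      spacing = c(1, 1, 3.6)
    ), class = "volume_stack")
  })
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf(
    "volume_stack %s: %d slices (%dx%d), %d tumor slice(s), GG-RP %d, GG-NB %d\n",
    x$patient_id, length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
    sum(x$tumor_flags), x$gg_rp, x$gg_nb))
  invisible(x)
}

#' Simulate a cohort of phantom volumes
#'
#' Draws `spec$n_patients` true grades from `spec$grade_probs`, simulates one
#' volume per patient via [generate_patient()] and assigns train/val/test
#' splits by a deterministic stratified rule: within each grade, patients in
#' simulation order fill the train, then val, then test quota given by
#' `split_fractions`.
#'
#' @param spec a [phantom_spec()].
#' @param split_fractions named numeric vector over train/val/test, summing
#'   to 1.
#' @return a list with `volumes` (list of `volume_stack`) and `manifest`
#'   (data.frame with patient_id, path, gg_rp, gg_nb, split, n_slices and a
#'   compact 0/1 string of tumor flags).
#' @export
generate_cohort <- function(spec,
                            split_fractions = c(train = 0.7, val = 0.1, test = 0.2)) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  stop_if_not(abs(sum(split_fractions) - 1) < 1e-9 &&
                all(c("train", "val", "test") %in% names(split_fractions)),
              "split_fractions must be named train/val/test and sum to 1")
  n <- spec$n_patients
  grades <- .draw_grades(spec)
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    volumes[[i]] <- generate_patient(spec, grades[i],
                                     seed = derive_seed(spec$seed, i),
                                     patient_id = sprintf("P%04d", i))
  }
  split <- character(n)
  for (gr in 1:5) {
    idx <- which(grades == gr)
    m <- length(idx)
    if (!m) next
    n_train <- round(m * split_fractions[["train"]])
    n_val <- round(m * split_fractions[["val"]])
    if (n_train + n_val > m) n_val <- m - n_train
    lab <- rep("test", m)
    lab[seq_len(n_train)] <- "train"
    if (n_val > 0) lab[n_train + seq_len(n_val)] <- "val"
    split[idx] <- lab
  }
  manifest <- data.frame(
    patient_id = vapply(volumes, `[[`, "", "patient_id"),
    path = NA_character_,
    gg_rp = grades,
    gg_nb = vapply(volumes, `[[`, 0L, "gg_nb"),
    split = split,
    n_slices = vapply(volumes, function(v) length(v$slices), 0L),
    tumor_flags = vapply(volumes, function(v)
      paste(as.integer(v$tumor_flags), collapse = ""), ""),
    stringsAsFactors = FALSE
  )
  structure(list(volumes = volumes, manifest = manifest, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d patients (seed %d)\n",
              nrow(x$manifest), x$spec$seed))
  print(table(grade = x$manifest$gg_rp, split = x$manifest$split))
  invisible(x)
}

#' @rdname generate_cohort
#' @param object a `phantom_spec`.
#' @param nsim number of patients (overrides `object$n_patients` if given).
#' @param seed optional seed override.
#' @param ... unused.
#' @export
simulate.phantom_spec <- function(object, nsim = object$n_patients,
                                  seed = object$seed, ...) {
  object$n_patients <- as.integer(nsim)
  object$seed <- as.integer(seed)
  generate_cohort(object)
}
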