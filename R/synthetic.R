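#' Default q-grid for synthetic benchmarks
#'
#' 600 points on \[0.008, 0.9\] 1/Angstrom: the dense grid of a modern
#' measurement, extending into the wide-angle regime the way profile
#' calculators evaluate model curves. The wide-angle region carries the
#' internal-structure detail that distinguishes individual conformers.
#'
#' @return Numeric q-grid.
#' @export
default_q_grid <- function() seq(0.008, 0.9, length.out = 600)

# sphere form-factor amplitude, F(0) = 1; series below x = 0.05 avoids
# the catastrophic cancellation of sin(x) - x cos(x) ~ x^3/3
sphere_ff <- function(q, R) {
  x <- q * R
  out <- 1 - x^2 / 10 + x^4 / 280
  nz <- x > 0.05
  out[nz] <- 3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3
  out
}

# multi-sphere Debye intensity for bodies at positions `pos` (rows) with
# radii `R` and contrasts `rho`; normalized to I(0) = 1, analytic Rg
multi_sphere_profile <- function(q, pos, R, rho = rep(1, length(R))) {
  A <- rho * R^3
  Fq <- vapply(R, sphere_ff, numeric(length(q)), q = q)
  D <- as.matrix(stats::dist(pos))
  I <- numeric(length(q))
  for (a in seq_along(R)) {
    I <- I + A[[a]]^2 * Fq[, a]^2
    if (a < length(R)) for (b in (a + 1):length(R)) {
      x <- q * D[a, b]
      sinc <- ifelse(x < 1e-8, 1, sin(x) / x)
      I <- I + 2 * A[[a]] * A[[b]] * Fq[, a] * Fq[, b] * sinc
    }
  }
  atot <- sum(A)
  com <- colSums(pos * A) / atot
  rg2 <- sum(A * (0.6 * R^2 + rowSums(sweep(pos, 2, com)^2))) / atot
  list(intensity = I / atot^2, rg = sqrt(rg2))
}

# classic two-sphere special case used by tests and docs
two_sphere_profile <- function(q, r1, r2, d, rho = c(1, 1)) {
  if (r2 <= 0)
    return(multi_sphere_profile(q, matrix(0, 1, 3), r1, rho[[1]]))
  multi_sphere_profile(q, rbind(c(0, 0, 0), c(d, 0, 0)), c(r1, r2), rho)
}

#' Generate a synthetic two-domain structural library
#'
#' Each conformer is built in two layers. The envelope is an analytic
#' multi-sphere Debye scatterer: two globular core domains of radii r1,
#' r2 at center separation d (the two-domain protein whose flexible
#' linker samples different domain distances), plus `n_satellites`
#' smaller spheres at conformer-specific positions standing in for
#' loops, termini and linker density. On top of the envelope, each
#' conformer carries private internal fine structure -- a random-phase
#' sum of cosine components over the molecule's internal distance range
#' -- standing in for the all-atom pair-distance detail that
#' distinguishes real conformers of similar overall shape. The fine
#' structure is suppressed at low q (so the Guinier region and the
#' analytic radius of gyration stay those of the envelope) and reaches
#' relative amplitude `fine_structure` in the wide-angle region. Without
#' it, a coarse-grained library is so mutually redundant that no
#' ensemble inference could single out individual members; with it, the
#' library behaves like a library of genuinely distinct conformers.
#' Profiles are normalized to I(0) = 1; the analytic radius of gyration
#' of each conformer is stored in the `geometry` attribute.
#'
#' @param n Number of conformers.
#' @param q q-grid (1/Angstrom).
#' @param r1_range,r2_range Core-domain radius ranges (Angstrom), sampled
#'   uniformly; mild variation mimics flexible termini.
#' @param d_range Center-separation range (Angstrom).
#' @param n_satellites Satellite spheres per conformer (0 gives the bare
#'   two-sphere model).
#' @param sat_r_range Satellite radius range (Angstrom).
#' @param sat_dist_range Satellite anchor distance range from a randomly
#'   chosen core center (Angstrom).
#' @param fine_structure Relative amplitude of the conformer-specific
#'   internal fine structure at wide angles (0 disables it).
#' @param n_modes Number of random-phase distance components per
#'   conformer.
#' @param mode_d_range Internal distance range of the fine-structure
#'   components (Angstrom).
#' @param rho Relative contrasts of the two core domains.
#' @param seed RNG seed.
#' @return A [structural_library()] with a `geometry` tibble attribute
#'   (`id`, `r1`, `r2`, `d`, `rg`).
#' @export
make_profile_library <- function(n, q = default_q_grid(),
                                 r1_range = c(14, 18), r2_range = c(10, 14),
                                 d_range = c(15, 65), n_satellites = 3,
                                 sat_r_range = c(6, 10),
                                 sat_dist_range = c(10, 30),
                                 fine_structure = 0.06, n_modes = 60,
                                 mode_d_range = c(5, 120), rho = c(1, 1),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  profs <- matrix(NA_real_, n, length(q))
  rg <- numeric(n)
  r1 <- numeric(n); r2 <- numeric(n); d <- numeric(n)
  ramp <- 1 - exp(-(q / 0.15)^2)  # fine structure absent from Guinier region
  for (i in seq_len(n)) {
    r1[[i]] <- runif(1, r1_range[[1]], r1_range[[2]])
    r2[[i]] <- runif(1, r2_range[[1]], r2_range[[2]])
    d[[i]] <- runif(1, d_range[[1]], d_range[[2]])
    if (r2[[i]] <= 0) {
      pos <- matrix(0, 1, 3)
      R <- r1[[i]]
      contrast <- rho[[1]]
    } else {
      pos <- rbind(c(0, 0, 0), c(d[[i]], 0, 0))
      R <- c(r1[[i]], r2[[i]])
      contrast <- rho
    }
    for (s in seq_len(n_satellites)) {
      anchor <- pos[sample.int(min(2L, nrow(pos)), 1L), ]
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pos <- rbind(pos, anchor + dir * runif(1, sat_dist_range[[1]],
                                             sat_dist_range[[2]]))
      R <- c(R, runif(1, sat_r_range[[1]], sat_r_range[[2]]))
      contrast <- c(contrast, 1)
    }
    p <- multi_sphere_profile(q, pos, R, contrast)
    I <- p$intensity
    if (fine_structure > 0 && n_modes > 0) {
      dk <- runif(n_modes, mode_d_range[[1]], mode_d_range[[2]])
      ph <- runif(n_modes, 0, 2 * pi)
      ak <- rnorm(n_modes, 0, 1 / sqrt(n_modes))
      g <- as.vector(cos(outer(q, dk) +
                           matrix(ph, length(q), n_modes, byrow = TRUE)) %*% ak)
      I <- I * (1 + fine_structure * ramp * g)
    }
    profs[i, ] <- I
    rg[[i]] <- p$rg
  }
  ids <- sprintf("conf_%03d", seq_len(n))
  lib <- structural_library(ids = ids, q = q, profiles = profs)
  attr(lib, "geometry") <- tibble(id = ids, r1 = r1, r2 = r2, d = d, rg = rg)
  lib
}

#' Noise specification for synthetic measurements
#'
#' The error template follows the standard recipe for simulating
#' counting-statistics errors on a model curve: errors proportional to
#' the intensity with a relative error that grows linearly in q,
#' \eqn{\varepsilon_{ref}(q) = c \, I(q) \, (q + q_{off})}, with `c` set
#' so the reference noise level (`sigma_scale = 1`) gives the stated
#' mean signal-to-noise over the curve. `sigma_scale` multiplies the
#' whole template, mirroring noise ladders quoted in multiples of an
#' experimental reference level.
#'
#' @param sigma_scale Noise multiplier relative to the reference level
#'   (>= 0; 0 gives noise-free data).
#' @param snr Mean signal-to-noise at `sigma_scale = 1`.
#' @param q_off Offset of the linear relative-error growth (1/Angstrom);
#'   sets the low-q floor of the relative error.
#' @param ref_error Optional explicit per-point error template overriding
#'   the parametric form.
#' @param seed RNG seed for the added noise.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(sigma_scale = 1, snr = 50, q_off = 0.03,
                       ref_error = NULL, seed = NULL) {
  if (sigma_scale < 0) abort("sigma_scale must be >= 0")
  structure(list(sigma_scale = sigma_scale, snr = snr, q_off = q_off,
                 ref_error = ref_error, seed = seed),
            class = "noise_spec")
}

#' Simulate a noisy ensemble-averaged SAXS measurement
#'
#' Forms the exact weighted-average curve of the true subset, adds
#' Gaussian noise \eqn{\eta_j \sim N(0, (\sigma \cdot
#' \varepsilon_{ref,j})^2)} and reports the truthful error column. The
#' ground truth (subset, weights, noise settings) is returned alongside
#' so downstream tests never have to re-derive it.
#'
#' @param library A [structural_library()].
#' @param true_ids Ids (or indices) of the generating conformers.
#' @param true_weights Simplex weights over `true_ids`.
#' @param noise A [noise_spec()].
#' @return List with `curve` (a [saxs_curve()]) and `truth` (list:
#'   `ids`, `weights`, `sigma_scale`, `ref_error`, `seed`).
#' @export
simulate_measurement <- function(library, true_ids, true_weights,
                                 noise = noise_spec()) {
  sub <- subset_library(library, true_ids)
  w <- true_weights / sum(true_weights)
  if (abs(sum(true_weights) - 1) > 1e-9)
    abort("true_weights must sum to 1")
  truth_curve <- as.vector(w %*% sub$profiles)
  q <- library$q
  eps_ref <- noise$ref_error %||% {
    cc <- mean(1 / (q + noise$q_off)) / noise$snr
    cc * truth_curve * (q + noise$q_off)
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)
  eps <- noise$sigma_scale * eps_ref
  m <- truth_curve + rnorm(length(q), 0, eps)
  # a strictly positive error column is required; for noise-free data a
  # vanishing floor keeps the curve valid without perturbing any fit
  eps_out <- pmax(eps, eps_ref * 1e-9)
  list(curve = saxs_curve(q, m, eps_out),
       truth = list(ids = sub$ids, weights = as.numeric(w),
                    sigma_scale = noise$sigma_scale,
                    ref_error = eps_ref, seed = noise$seed))
}

#' Simulate per-conformer chemical-shift predictions and experiment
#'
#' Per-shift base values are drawn in a typical amide-proton window and
#' each conformer is offset from the base by conformation-dependent
#' perturbations; the experimental shifts are the truth-weighted mean
#' plus Gaussian noise with the combined variance
#' \eqn{\varepsilon_{CS}^2 + \varepsilon_{pre}^2}.
#'
#' @param n_conformers Library size.
#' @param n_shifts Number of measured shifts.
#' @param true_idx Indices of generating conformers.
#' @param true_weights Simplex weights over `true_idx`.
#' @param eps_cs Prediction uncertainty (ppm).
#' @param eps_pre Experimental error (ppm).
#' @param spread Conformer-to-conformer shift spread (ppm).
#' @param seed RNG seed.
#' @return List with `cs_pred` (conformers x shifts), `cs_pred_err`,
#'   `cs_data` (a [chemical_shift_data()]), `labels`.
#' @export
simulate_cs <- function(n_conformers, n_shifts, true_idx, true_weights,
                        eps_cs = 0.1, eps_pre = 0.05, spread = 0.3,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("res%03d_HN", seq_len(n_shifts))
  base <- runif(n_shifts, 6.5, 9.5)
  cs_pred <- matrix(rep(base, each = n_conformers) +
                      rnorm(n_conformers * n_shifts, 0, spread),
                    nrow = n_conformers)
  colnames(cs_pred) <- labels
  w <- true_weights / sum(true_weights)
  truth <- as.vector(w %*% cs_pred[true_idx, , drop = FALSE])
  v <- eps_cs^2 + eps_pre^2
  shifts <- truth + rnorm(n_shifts, 0, sqrt(v))
  list(cs_pred = cs_pred, cs_pred_err = rep(eps_cs, n_shifts),
       cs_data = chemical_shift_data(labels, shifts, eps_pre),
       labels = labels)
}

#' Assign structural energies favoring a true subset
#'
#' Members of the true subset receive the lowest energies (by default the
#' quintet -135.2, -140.0, -126.7, -125.5, -124.0 when the subset has 5
#' members); all other conformers sit at least `gap` energy units higher,
#' so the Boltzmann-biased prior carries real information about the
#' generating ensemble. `gap = 0` makes the energies uninformative.
#'
#' @param library A [structural_library()] (or its size).
#' @param true_ids Ids or indices of the favored subset.
#' @param gap Minimum energy separation between the subset and the rest.
#' @param truth_energies Optional explicit energies for the subset.
#' @param spread Spread of the non-subset energies above the gap.
#' @param seed RNG seed.
#' @return Numeric energy vector over the library.
#' @export
assign_energies <- function(library, true_ids, gap = 8,
                            truth_energies = NULL, spread = 10,
                            seed = NULL) {
  n <- if (inherits(library, "structural_library")) length(library$ids)
  else as.integer(library)
  idx <- if (is.character(true_ids)) match(true_ids, library$ids)
  else as.integer(true_ids)
  k <- length(idx)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth_energies)) {
    truth_energies <- if (k == 5L) c(-135.2, -140.0, -126.7, -125.5, -124.0)
    else sort(runif(k, -140, -124))
  }
  U <- numeric(n)
  U[idx] <- truth_energies
  rest <- setdiff(seq_len(n), idx)
  U[rest] <- max(truth_energies) + gap + runif(length(rest), 0, spread)
  U
}

#' Root-mean-square deviation between inferred and true weights
#'
#' Weights are aligned by member id over the union of the two supports:
#' a true member missing from the inferred set contributes its full truth
#' weight as error, and an extra inferred member contributes its inferred
#' weight. Symmetric in its arguments.
#'
#' @param inferred Named weight vector (names = member ids).
#' @param truth Named weight vector.
#' @return RMSD over the union of members.
#' @export
weight_rmsd <- function(inferred, truth) {
  ids <- union(names(inferred), names(truth))
  wi <- setNames(rep(0, length(ids)), ids)
  wt <- wi
  wi[names(inferred)] <- inferred
  wt[names(truth)] <- truth
  sqrt(mean((wi - wt)^2))
}

#' Preset synthetic benchmark scenarios
#'
#' Bundled generator settings matching the package's standard benchmark
#' experiments:
#' \describe{
#'   \item{`evidence10`}{10-member library, 3-member truth with weights
#'     (0.2, 0.3, 0.5) -- sized for an exhaustive evidence scan. Uses an
#'     experimental-length grid (150 points to 0.35 1/Angstrom), a
#'     high-quality reference curve (mean signal-to-noise 200) and bare
#'     multi-sphere profiles (no fine structure): ten conformers of one
#'     protein measured on a short grid are mutually correlated, which is
#'     the regime in which the evidence's complexity penalty visibly
#'     separates ensemble sizes.}
#'   \item{`recovery100`}{100-member library, 5-member truth with weights
#'     (0.1, 0.15, 0.2, 0.25, 0.3), reference noise.}
#'   \item{`lownoise100`}{As `recovery100` at near-zero noise
#'     (`sigma_scale = 0.01`).}
#'   \item{`energy100`}{As `recovery100` with equal truth weights 0.2 and
#'     the energy quintet (-135.2, -140.0, -126.7, -125.5, -124.0)
#'     assigned to the truth members. The matching thermal scale
#'     `kT = 15` (force-field units) is returned alongside: it maps the
#'     quintet to moderately informative Boltzmann populations
#'     (~0.13-0.34) rather than a delta on the single lowest-energy
#'     member, the regime in which an energy prior carries useful
#'     information about the whole generating ensemble.}
#'   \item{`refined101`}{As `energy100` plus a 101st energy-refined
#'     conformer at -178.9 whose profile duplicates the lowest-energy
#'     member, for prior-robustness experiments.}
#' }
#'
#' @param preset One of the scenario names.
#' @param seed RNG seed controlling library geometry, truth draw and
#'   noise.
#' @param sigma_scale Optional noise-level override.
#' @return List with `library`, `curve`, `truth`, and (energy presets)
#'   `energies`.
#' @export
synthetic_benchmark <- function(preset = c("evidence10", "recovery100",
                                           "lownoise100", "energy100",
                                           "refined101"),
                                seed = 1, sigma_scale = NULL) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  gen <- switch(preset,
    evidence10 = list(n = 10, k = 3, w = c(0.2, 0.3, 0.5), sigma = 1,
                      energies = FALSE, fs = 0, snr = 200,
                      q = seq(0.008, 0.35, length.out = 150)),
    recovery100 = list(n = 100, k = 5, w = c(0.1, 0.15, 0.2, 0.25, 0.3),
                       sigma = 1, energies = FALSE),
    lownoise100 = list(n = 100, k = 5, w = c(0.1, 0.15, 0.2, 0.25, 0.3),
                       sigma = 0.01, energies = FALSE),
    energy100 = list(n = 100, k = 5, w = rep(0.2, 5), sigma = 1,
                     energies = TRUE),
    refined101 = list(n = 100, k = 5, w = rep(0.2, 5), sigma = 1,
                      energies = TRUE, refined = TRUE))
  if (!is.null(sigma_scale)) gen$sigma <- sigma_scale
  lib <- make_profile_library(gen$n, q = gen$q %||% default_q_grid(),
                              fine_structure = gen$fs %||% 0.06,
                              seed = seed)
  set.seed(seed + 7L)
  true_idx <- sort(sample.int(gen$n, gen$k))
  energies <- NULL
  if (isTRUE(gen$energies)) {
    energies <- assign_energies(lib, true_idx, seed = seed + 13L)
    if (isTRUE(gen$refined)) {
      # duplicate the lowest-energy truth member with a deeply refined score
      low <- true_idx[[which.min(energies[true_idx])]]
      prof <- lib$profiles[low, ] * (1 + 1e-4)
      lib <- structural_library(
        ids = c(lib$ids, "conf_refined"), q = lib$q,
        profiles = rbind(lib$profiles, prof))
      energies <- c(energies, -178.9)
    }
    lib <- structural_library(ids = lib$ids, q = lib$q,
                              profiles = lib$profiles, energies = energies)
  }
  sim <- simulate_measurement(lib, true_idx, gen$w,
                              noise_spec(sigma_scale = gen$sigma,
                                         snr = gen$snr %||% 50,
                                         seed = seed + 29L))
  out <- list(library = lib, curve = sim$curve, truth = sim$truth)
  if (!is.null(energies)) {
    out$energies <- energies
    out$kT <- 15
  }
  out
}
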