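#' Cohort recipe for the dichotomized-Gaussian generator
#'
#' Describes a synthetic binary symptom cohort: each variable i is 1 when
#' a latent standard-normal variate exceeds the (1 - prevalence_i)
#' quantile, and pairwise dependence is induced by a latent correlation
#' matrix. This latent-threshold (dichotomized-Gaussian) model reproduces
#' arbitrary marginal prevalences and calibrated pairwise MI while keeping
#' positive semidefiniteness the only joint-consistency condition.
#'
#' @param n_patients number of rows to generate (>= 2).
#' @param prevalences named numeric vector of marginal prevalences in
#'   (0, 1); names become variable names.
#' @param latent either `NULL` (independence), a symmetric latent
#'   correlation matrix with unit diagonal, or a data.frame with columns
#'   `var1`, `var2`, `target_mi_bits` of planted pairwise dependencies
#'   (calibrated to latent correlations via [calibrate_latent_rho()]).
#' @param seed integer seed.
#' @param cohort_label label carried onto generated matrices.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, prevalences, latent = NULL, seed = 1,
                        cohort_label = "synthetic") {
  if (is.null(names(prevalences)) || any(!nzchar(names(prevalences)))) {
    stop("`prevalences` must be a named vector")
  }
  if (any(prevalences <= 0 | prevalences >= 1)) {
    stop("prevalences must lie strictly in (0, 1)")
  }
  k <- length(prevalences)
  if (n_patients < 2) stop("`n_patients` must be >= 2")
  if (is.data.frame(latent)) {
    stopifnot(all(c("var1", "var2", "target_mi_bits") %in% names(latent)))
    Sigma <- diag(k)
    dimnames(Sigma) <- list(names(prevalences), names(prevalences))
    for (r in seq_len(nrow(latent))) {
      i <- match(latent$var1[r], names(prevalences))
      j <- match(latent$var2[r], names(prevalences))
      if (is.na(i) || is.na(j)) stop("dependency names not in `prevalences`")
      rho <- calibrate_latent_rho(prevalences[i], prevalences[j],
                                  latent$target_mi_bits[r])$latent_rho
      Sigma[i, j] <- Sigma[j, i] <- rho
    }
    latent <- Sigma
  }
  if (!is.null(latent)) {
    stopifnot(is.matrix(latent), nrow(latent) == k, ncol(latent) == k)
    if (max(abs(latent - t(latent))) > 1e-10 || any(abs(diag(latent) - 1) > 1e-10)) {
      stop("latent matrix must be symmetric with unit diagonal")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 prevalences = prevalences,
                 latent = latent,
                 seed = as.integer(seed),
                 cohort_label = cohort_label),
            class = "cohort_spec")
}

#' Generate a synthetic binary symptom cohort
#'
#' Draws the latent multivariate normal implied by the spec's correlation
#' matrix and thresholds each variable at the (1 - prevalence) standard
#' normal quantile. Deterministic for a fixed spec seed. A latent matrix
#' with smallest eigenvalue below -1e-8 is rejected (the error names the
#' eigenvalue); eigenvalues in (-1e-8, 0) are clipped to zero with a
#' message (never silently).
#'
#' @param spec a [cohort_spec()].
#' @return a [symptom_matrix].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- length(spec$prevalences)
  n <- spec$n_patients
  Sigma <- spec$latent
  if (is.null(Sigma)) Sigma <- diag(k)
  eig <- eigen(Sigma, symmetric = TRUE)
  lam <- eig$values
  if (min(lam) < -1e-8) {
    stop(sprintf("latent matrix is not positive semidefinite (smallest eigenvalue %.3e)",
                 min(lam)))
  }
  if (min(lam) < 0) {
    message(sprintf("latent matrix nearly singular (smallest eigenvalue %.3e); clipping to PSD",
                    min(lam)))
    lam <- pmax(lam, 0)
  }
  L <- eig$vectors %*% diag(sqrt(lam), k)
  Z <- with_local_seed(spec$seed, matrix(stats::rnorm(n * k), n, k) %*% t(L))
  thresholds <- stats::qnorm(1 - spec$prevalences)
  X <- matrix(0L, n, k, dimnames = list(NULL, names(spec$prevalences)))
  for (i in seq_len(k)) X[, i] <- as.integer(Z[, i] > thresholds[i])
  symptom_matrix(X, cohort_label = spec$cohort_label)
}

# P(Z1 > h, Z2 > t) for standard bivariate normal with correlation rho,
# by 1-D reduction and adaptive quadrature.
bvn_upper_orthant <- function(h, t, rho) {
  if (abs(rho) >= 1) {
    # comonotone limit
    if (rho >= 1) return(stats::pnorm(max(h, t), lower.tail = FALSE))
    p <- stats::pnorm(h, lower.tail = FALSE) - stats::pnorm(-t)
    return(max(p, 0))
  }
  if (rho == 0) {
    return(stats::pnorm(h, lower.tail = FALSE) * stats::pnorm(t, lower.tail = FALSE))
  }
  s <- sqrt(1 - rho^2)
  f <- function(z) {
    stats::dnorm(z) * stats::pnorm((t - rho * z) / s, lower.tail = FALSE)
  }
  stats::integrate(f, h, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Population MI (bits) of a dichotomized bivariate normal pair.
latent_pair_mi <- function(prev_x, prev_y, rho) {
  hx <- stats::qnorm(1 - prev_x)
  hy <- stats::qnorm(1 - prev_y)
  p11 <- bvn_upper_orthant(hx, hy, rho)
  p10 <- prev_x - p11
  p01 <- prev_y - p11
  p00 <- 1 - p11 - p10 - p01
  p <- pmax(c(p00, p01, p10, p11), 0)
  px <- c(1 - prev_x, 1 - prev_x, prev_x, prev_x)
  py <- c(1 - prev_y, prev_y, 1 - prev_y, prev_y)
  sum(ifelse(p > 0, p * log2(p / (px * py)), 0))
}

#' Calibrate a latent correlation to a target mutual information
#'
#' Finds the latent Gaussian correlation rho in \[0, 1) such that
#' thresholding a bivariate normal at the two prevalence quantiles yields
#' a pair with population MI equal to `target_mi_bits`, by monotone
#' bisection on rho (population MI is computed from the bivariate normal
#' orthant probability by numerical integration).
#'
#' @param prev_x,prev_y marginal prevalences in (0, 1).
#' @param target_mi_bits desired MI in bits; must not exceed the smaller
#'   marginal entropy.
#' @param tol calibration tolerance in bits (default 1e-4).
#' @return list of class `calibration_result` with `latent_rho`,
#'   `achieved_mi_bits`, `target_mi_bits`, `tolerance`.
#' @export
calibrate_latent_rho <- function(prev_x, prev_y, target_mi_bits, tol = 1e-4) {
  stopifnot(prev_x > 0, prev_x < 1, prev_y > 0, prev_y < 1, tol > 0,
            target_mi_bits >= 0)
  h_bound <- min(binary_entropy(prev_x), binary_entropy(prev_y))
  if (target_mi_bits > h_bound) {
    stop(sprintf("target MI %.4f bits exceeds the entropy bound %.4f bits",
                 target_mi_bits, h_bound))
  }
  if (target_mi_bits == 0) {
    return(structure(list(latent_rho = 0, achieved_mi_bits = 0,
                          target_mi_bits = 0, tolerance = tol),
                     class = "calibration_result"))
  }
  rho_hi <- 1 - 1e-9
  mi_max <- latent_pair_mi(prev_x, prev_y, rho_hi)
  if (target_mi_bits > mi_max + tol) {
    stop(sprintf(
      "target MI %.4f bits unattainable for prevalences %.3f/%.3f (max %.4f bits at rho -> 1; entropy bound %.4f)",
      target_mi_bits, prev_x, prev_y, mi_max, h_bound))
  }
  lo <- 0; hi <- rho_hi
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    mi_mid <- latent_pair_mi(prev_x, prev_y, mid)
    if (abs(mi_mid - target_mi_bits) <= tol / 2) break
    if (mi_mid < target_mi_bits) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  structure(list(latent_rho = mid,
                 achieved_mi_bits = latent_pair_mi(prev_x, prev_y, mid),
                 target_mi_bits = target_mi_bits,
                 tolerance = tol),
            class = "calibration_result")
}

#' Canonical planted test structures
#'
#' Convenience constructor for the three cohort structures used to
#' validate the pipeline: `"global-null"` (fully independent variables),
#' `"two-block"` (two modules with within-block dependence and none
#' between), and `"core-periphery"` (a densely tied core with each
#' periphery node attached to the core only).
#'
#' @param kind one of `"global-null"`, `"two-block"`, `"core-periphery"`.
#' @param n_patients cohort size (default 500).
#' @param k number of variables for `"global-null"`.
#' @param block_sizes integer pair for `"two-block"`.
#' @param core_size,periphery_size sizes for `"core-periphery"`.
#' @param effect_mi_bits within-structure MI target in bits (default 0.2;
#'   core-periphery attachments use half the core-core effect).
#' @param prevalence common marginal prevalence (default 0.5).
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
planted_structure_spec <- function(kind = c("global-null", "two-block",
                                            "core-periphery"),
                                   n_patients = 500, k = 10,
                                   block_sizes = c(5, 5),
                                   core_size = 5, periphery_size = 8,
                                   effect_mi_bits = 0.2, prevalence = 0.5,
                                   seed = 1) {
  kind <- match.arg(kind)
  if (kind == "global-null") {
    prev <- stats::setNames(rep(prevalence, k), sprintf("v%02d", seq_len(k)))
    return(cohort_spec(n_patients, prev, latent = NULL, seed = seed,
                       cohort_label = "global-null"))
  }
  if (kind == "two-block") {
    k1 <- block_sizes[1]; k2 <- block_sizes[2]
    kk <- k1 + k2
    prev <- stats::setNames(rep(prevalence, kk),
                            c(sprintf("a%02d", seq_len(k1)),
                              sprintf("b%02d", seq_len(k2))))
    rho <- calibrate_latent_rho(prevalence, prevalence,
                                effect_mi_bits)$latent_rho
    Sigma <- diag(kk)
    Sigma[seq_len(k1), seq_len(k1)] <- rho
    Sigma[k1 + seq_len(k2), k1 + seq_len(k2)] <- rho
    diag(Sigma) <- 1
    dimnames(Sigma) <- list(names(prev), names(prev))
    return(cohort_spec(n_patients, prev, latent = Sigma, seed = seed,
                       cohort_label = "two-block"))
  }
  kk <- core_size + periphery_size
  prev <- stats::setNames(rep(prevalence, kk),
                          c(sprintf("core%02d", seq_len(core_size)),
                            sprintf("peri%02d", seq_len(periphery_size))))
  rho_cc <- calibrate_latent_rho(prevalence, prevalence,
                                 effect_mi_bits)$latent_rho
  rho_cp <- calibrate_latent_rho(prevalence, prevalence,
                                 effect_mi_bits / 2)$latent_rho
  Sigma <- diag(kk)
  core_idx <- seq_len(core_size)
  Sigma[core_idx, core_idx] <- rho_cc
  # pendant attachment: each periphery node depends on one core node only,
  # which keeps the joint latent matrix comfortably positive semidefinite
  for (p in seq_len(periphery_size)) {
    anchor <- core_idx[(p - 1) %% core_size + 1]
    Sigma[core_size + p, anchor] <- rho_cp
    Sigma[anchor, core_size + p] <- rho_cp
  }
  diag(Sigma) <- 1
  dimnames(Sigma) <- list(names(prev), names(prev))
  eig_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (eig_min < -1e-8) {
    stop(sprintf("core-periphery latent matrix not PSD (smallest eigenvalue %.3e); reduce the effect",
                 eig_min))
  }
  cohort_spec(n_patients, prev, latent = Sigma, seed = seed,
              cohort_label = "core-periphery")
}

#' Reference prevalence profiles for tic-disorder cohorts
#'
#' Published lifetime prevalence counts of 24 symptoms and tic-related
#' phenomena in a young (n = 529) and an adult (n = 503) chronic
#' tic-disorder cohort, including the near-degenerate simple-motor-tics
#' variable (present in all but one patient in each cohort). Useful as a
#' realistic marginal profile for synthetic cohorts; the counts describe
#' marginals only, not the joint distribution.
#'
#' @param cohort `"young"` or `"adult"`.
#' @return data.frame with columns `variable`, `count`, `n_patients`,
#'   `prevalence`.
#' @export
ctd_prevalence_profile <- function(cohort = c("young", "adult")) {
  cohort <- match.arg(cohort)
  vars <- c("simple motor tics", "simple vocal tics", "complex motor tics",
            "complex vocal tics", "coprolalia", "copropraxia", "palilalia",
            "echolalia", "echopraxia", "touching people", "touching objects",
            "obsessions", "compulsions", "anxiety", "depression",
            "substance use disorder", "premonitory urges",
            "tic suppression", "hyperactivity", "inattention",
            "self-injurious behavior", "aggression toward others",
            "impulsivity", "sleep disorders")
  if (cohort == "young") {
    n <- 529L
    counts <- c(528L, 498L, 275L, 251L, 113L, 80L, 157L, 130L, 88L, 126L,
                193L, 105L, 300L, 149L, 41L, 3L, 296L, 391L, 153L, 235L,
                179L, 59L, 317L, 117L)
  } else {
    n <- 503L
    counts <- c(502L, 471L, 287L, 267L, 132L, 80L, 182L, 160L, 150L, 106L,
                211L, 252L, 405L, 174L, 195L, 91L, 404L, 462L, 138L, 170L,
                226L, 50L, 277L, 156L)
  }
  data.frame(variable = vars, count = counts, n_patients = n,
             prevalence = counts / n, stringsAsFactors = FALSE)
}

#' Read or write a cohort spec as YAML
#'
#' @param spec a [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec` returns `path` invisibly;
#'   `read_cohort_spec` returns a [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- list(n_patients = spec$n_patients,
              cohort_label = spec$cohort_label,
              seed = spec$seed,
              prevalences = as.list(spec$prevalences))
  if (!is.null(spec$latent)) {
    # serialize rows as %.17g strings so correlations round-trip exactly
    obj$latent <- apply(spec$latent, 1, function(r) sprintf("%.17g", r),
                        simplify = FALSE)
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  prev <- unlist(obj$prevalences)
  latent <- NULL
  if (!is.null(obj$latent)) {
    latent <- do.call(rbind, lapply(obj$latent, as.numeric))
    dimnames(latent) <- list(names(prev), names(prev))
  }
  cohort_spec(obj$n_patients, prev, latent = latent, seed = obj$seed,
              cohort_label = obj$cohort_label)
}
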