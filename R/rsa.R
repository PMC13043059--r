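#' Full Spearman correlation between two RDMs
#'
#' Spearman rank correlation over the lower-triangle vectors (average ranks
#' for ties).
#'
#' @param a,b [rdm()] objects over the same condition set and ordering.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman_rdm_corr <- function(a, b) {
  check_same_conditions(a, b)
  va <- rdm_vec(a); vb <- rdm_vec(b)
  stopifnot(length(va) >= 6)  # n >= 4 conditions
  if (stats::var(va) == 0 || stats::var(vb) == 0) {
    stop("zero-variance RDM vector; Spearman correlation undefined")
  }
  stats::cor(va, vb, method = "spearman")
}

check_same_conditions <- function(...) {
  rdms <- list(...)
  ids <- rownames(rdms[[1]])
  for (r in rdms[-1]) {
    if (nrow(r) != nrow(rdms[[1]]) || !identical(rownames(r), ids)) {
      stop("RDMs must share the same condition set and ordering")
    }
  }
  invisible(TRUE)
}

# Average-rank transform of an RDM's lower-triangle vector.
rank_vec <- function(x) rank(rdm_vec(x), ties.method = "average")

#' Partial Spearman correlation between RDMs
#'
#' Rank-transforms all lower-triangle vectors (average ranks for ties),
#' regresses the neural and target rank vectors on the control rank vectors
#' plus an intercept by least squares, and returns the Pearson correlation
#' of the two residual vectors. With no controls this equals the full
#' Spearman correlation.
#'
#' @param neural,target [rdm()] objects.
#' @param controls List of control [rdm()]s to partial out of both sides.
#' @param target_id,control_ids Optional labels carried into the result.
#' @return Object of class `rsa_result`: `coefficient`, `kind`
#'   ("full_spearman" or "partial_spearman"), `target_id`, `control_ids`.
#' @export
partial_spearman <- function(neural, target, controls = list(),
                             target_id = "target",
                             control_ids = names(controls)) {
  do.call(check_same_conditions, c(list(neural, target), controls))
  m <- length(rdm_vec(neural))
  if (length(controls) >= m - 2) {
    stop("too many control RDMs for the number of condition pairs")
  }
  rn <- rank_vec(neural)
  rt <- rank_vec(target)
  if (stats::var(rn) == 0) stop("constant ranks in the neural RDM")
  if (stats::var(rt) == 0) stop("constant ranks in the target RDM")
  if (length(controls) == 0) {
    co <- stats::cor(rn, rt)
    return(structure(list(coefficient = co, kind = "full_spearman",
                          target_id = target_id, control_ids = character()),
                     class = "rsa_result"))
  }
  rc <- vapply(controls, rank_vec, numeric(m))
  for (j in seq_len(ncol(rc))) {
    if (stats::var(rc[, j]) == 0) {
      stop("constant ranks in control RDM ",
           if (!is.null(control_ids)) control_ids[j] else j)
    }
  }
  X <- cbind(1, rc)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear control RDMs")
  res_n <- stats::lm.fit(X, rn)$residuals
  res_t <- stats::lm.fit(X, rt)$residuals
  if (stats::var(res_n) < .Machine$double.eps * stats::var(rn) ||
      stats::var(res_t) < .Machine$double.eps * stats::var(rt)) {
    stop("zero-variance residual after partialling out controls ",
         "(a control coincides with the neural or target RDM)")
  }
  structure(list(coefficient = stats::cor(res_n, res_t),
                 kind = "partial_spearman", target_id = target_id,
                 control_ids = if (is.null(control_ids)) {
                   as.character(seq_along(controls))
                 } else control_ids),
            class = "rsa_result")
}

#' @export
print.rsa_result <- function(x, ...) {
  cat(sprintf("<rsa_result  %s  %s = %.4f%s>\n", x$kind, x$target_id,
              x$coefficient,
              if (length(x$control_ids)) {
                paste0("  | controls: ", paste(x$control_ids, collapse = ", "))
              } else ""))
  invisible(x)
}

#' Group-level one-sample t-tests with BH-FDR correction
#'
#' One family per (model, region/time window) cell: a one-sample t-test of
#' the per-subject coefficients against 0 with the requested tail, then
#' Benjamini-Hochberg step-up correction of the p-values across the whole
#' family set.
#'
#' @param values Named list of numeric vectors (per-subject coefficients,
#'   one vector per family) or a data.frame with columns `family` and
#'   `value`.
#' @param tail "one" (upper-tailed, H1: coefficient > 0) or "two".
#' @return data.frame with columns `family`, `n`, `mean`, `t`, `dof`, `p`,
#'   `q`, `significant` (q < 0.05).
#' @export
group_ttest_fdr <- function(values, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (is.data.frame(values)) {
    values <- split(values$value, values$family)
  }
  stopifnot(length(values) >= 1)
  rows <- lapply(names(values), function(fam) {
    v <- values[[fam]]
    if (length(v) < 3) stop("fewer than 3 subjects in family ", fam)
    if (stats::var(v) == 0) stop("zero variance across subjects in family ", fam)
    tt <- stats::t.test(v, mu = 0,
                        alternative = if (tail == "one") "greater" else "two.sided")
    data.frame(family = fam, n = length(v), mean = mean(v),
               t = unname(tt$statistic), dof = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.05
  out
}

#' Paired task contrast of per-subject coefficients
#'
#' Paired t-test on the subject-wise differences (task A minus task B),
#' two-tailed, with BH-FDR across families when several contrasts are
#' supplied together.
#'
#' @param values_a,values_b Numeric vectors paired by subject, or named
#'   lists of such vectors (one per family).
#' @return data.frame with `family`, `n`, `mean_diff`, `t`, `dof`, `p`,
#'   `q`, `significant`.
#' @export
paired_contrast <- function(values_a, values_b) {
  if (!is.list(values_a)) values_a <- list(contrast = values_a)
  if (!is.list(values_b)) values_b <- list(contrast = values_b)
  stopifnot(identical(names(values_a), names(values_b)))
  rows <- lapply(names(values_a), function(fam) {
    a <- values_a[[fam]]; b <- values_b[[fam]]
    stopifnot(length(a) == length(b), length(a) >= 3)
    d <- a - b
    if (stats::var(d) == 0) stop("zero-variance differences in family ", fam)
    tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
    data.frame(family = fam, n = length(d), mean_diff = mean(d),
               t = unname(tt$statistic), dof = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.05
  out
}

#' Group RSA pipeline: unique contribution of each model per region
#'
#' For every subject, region and target model, computes the partial
#' Spearman correlation between the subject's neural RDM and the model RDM,
#' controlling for all other model RDMs; then runs group one-sample t-tests
#' with BH-FDR across all (model x region) families.
#'
#' @param neural Nested list: `neural[[region]][[subject]]` is an [rdm()].
#' @param models Named list of model [rdm()]s.
#' @param targets Names of the models to report (default: all); every model
#'   other than the current target is always partialled out.
#' @param tail Passed to [group_ttest_fdr()].
#' @return List with `coefficients` (data.frame region x model x subject)
#'   and `group` (the [group_ttest_fdr()] table with `region` and `model`
#'   columns).
#' @export
rsa_group_pipeline <- function(neural, models, targets = names(models),
                               tail = "one") {
  stopifnot(length(names(models)) == length(models))
  coef_rows <- list()
  for (region in names(neural)) {
    for (s in seq_along(neural[[region]])) {
      for (tg in targets) {
        ctrl <- models[setdiff(names(models), tg)]
        r <- partial_spearman(neural[[region]][[s]], models[[tg]],
                              controls = ctrl, target_id = tg)
        coef_rows[[length(coef_rows) + 1]] <-
          data.frame(region = region, model = tg, subject = s,
                     coefficient = r$coefficient)
      }
    }
  }
  coefs <- do.call(rbind, coef_rows)
  fams <- split(coefs$coefficient,
                paste(coefs$region, coefs$model, sep = ":"))
  grp <- group_ttest_fdr(fams, tail = tail)
  parts <- strsplit(grp$family, ":", fixed = TRUE)
  grp$region <- vapply(parts, `[`, "", 1)
  grp$model <- vapply(parts, `[`, "", 2)
  list(coefficients = coefs, group = grp)
}

#' Planted-dissociation recovery experiment
#'
#' Generates synthetic scenes, builds the two layout model RDMs (relative
#' distance, orientation) from exact ground truth, adds three nuisance
#' feature RDMs, and simulates two "regions" of several "subjects": one
#' region's neural RDM is a noisy monotone transform of the
#' relative-distance RDM, the other of the orientation RDM. The group
#' pipeline must recover the planted model (significant q) and reject the
#' non-planted one in each region. The noise SD is set from the closed-form
#' Pearson attenuation so that the planted full Spearman correlation is
#' approximately `target_rho`.
#'
#' @param n_subjects,n_conditions Simulated cohort dimensions.
#' @param seed Master seed.
#' @param target_rho Planted full-Spearman level (default 0.3).
#' @return List: `group` (group stats with `planted` flag), `coefficients`,
#'   `planted_full_spearman` (mean over subjects of the planted models'
#'   full Spearman correlations), `models`.
#' @export
planted_dissociation_experiment <- function(n_subjects = 8,
                                            n_conditions = 60, seed = 1,
                                            target_rho = 0.3) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 100L,
                                      n_conditions + 2L))
  # Layout model RDMs from exact synthetic ground truth.
  ori_feats <- matrix(0, n_conditions, 5)
  dist_feats <- matrix(0, n_conditions, 5)
  for (i in seq_len(n_conditions)) {
    scene <- sample_scene(seeds[i])
    ta <- truth_aerial(scene)
    walls <- list(
      list(orientation_deg = ta$orientation_side,
           phi_start_deg = -ta$fov_half, phi_end_deg = ta$mid[1]),
      list(orientation_deg = ta$orientation_mid,
           phi_start_deg = ta$mid[1], phi_end_deg = ta$mid[2]),
      list(orientation_deg = ta$orientation_side,
           phi_start_deg = ta$mid[2], phi_end_deg = ta$fov_half))
    walls <- Filter(function(w) w$phi_end_deg - w$phi_start_deg > 1e-9, walls)
    walls <- lapply(walls, function(w) {
      w$phi_start_deg <- max(w$phi_start_deg, -ta$fov_half)
      w$phi_end_deg <- min(w$phi_end_deg, ta$fov_half)
      w
    })
    ori_feats[i, ] <- orientation_feature(walls, fov_deg = 2 * ta$fov_half)
    dist_feats[i, ] <- reldist_feature(scene$seg)
  }
  models <- list(reldist = model_rdm(dist_feats, "cityblock"),
                 orientation = model_rdm(ori_feats, "cityblock"))
  # Nuisance feature RDMs (stand-ins for low/mid/high-level image models).
  models <- c(models, with_seed(seeds[n_conditions + 1L], {
    gist <- matrix(stats::rnorm(n_conditions * 20), n_conditions)
    tex <- matrix(stats::rnorm(n_conditions * 30), n_conditions)
    sem <- matrix(stats::rexp(n_conditions * 10), n_conditions)
    list(gist = model_rdm(gist, "euclidean"),
         texture = model_rdm(tex, "euclidean"),
         semantic = model_rdm(sem, "cosine"))
  }))

  m <- n_conditions * (n_conditions - 1) / 2
  var_rank <- (m^2 - 1) / 12
  noise_sd <- sqrt(var_rank * (1 / target_rho^2 - 1))
  plant <- function(model, sub_seed) {
    v <- rank(rdm_vec(model), ties.method = "average")
    noisy <- v + with_seed(sub_seed, stats::rnorm(m, 0, noise_sd))
    rdm_from_vec(noisy - min(noisy), n_conditions)
  }
  base <- seeds[n_conditions + 2L]
  neural <- list(
    distance_region = lapply(seq_len(n_subjects), function(s) {
      plant(models$reldist, base + 2L * s)
    }),
    orientation_region = lapply(seq_len(n_subjects), function(s) {
      plant(models$orientation, base + 2L * s + 1L)
    }))

  res <- rsa_group_pipeline(neural, models,
                            targets = c("reldist", "orientation"),
                            tail = "one")
  res$group$planted <-
    (res$group$region == "distance_region" & res$group$model == "reldist") |
    (res$group$region == "orientation_region" & res$group$model == "orientation")
  fs <- c(vapply(neural$distance_region, function(r) {
    spearman_rdm_corr(r, models$reldist)
  }, 0),
  vapply(neural$orientation_region, function(r) {
    spearman_rdm_corr(r, models$orientation)
  }, 0))
  res$planted_full_spearman <- mean(fs)
  res$models <- models
  res
}
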