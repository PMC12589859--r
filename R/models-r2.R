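#' Variance decomposition: marginal, conditional and semi-partial R2
#'
#' Marginal R2 is the variance explained by the fixed effects,
#' `s2_fixed / (s2_fixed + s2_family + s2_resid)`; conditional R2 adds the
#' family variance to the numerator. The unique contribution of each
#' predictor group is the semi-partial R2: the marginal R2 of the full
#' model minus that of a model refitted without the group and its
#' woodiness interaction, both on identical rows by REML. Semi-partials
#' measure uniquely attributable variance and do not sum to the full
#' marginal R2. Optional percentile confidence intervals come from a
#' parametric bootstrap (responses re-simulated from the fitted model,
#' every model refitted per draw).
#'
#' @param fit A drivers `troph_fit` (or any `troph_fit` for
#'   marginal/conditional only).
#' @param predictor_groups Named list mapping group labels to the model
#'   variable each group owns; defaults to the four drivers.
#' @param n_boot Parametric bootstrap draws for CIs; fewer than 2 omits
#'   CIs. 500 gives stable intervals; it is the expensive option.
#' @param seed Seed for the bootstrap.
#' @return A `troph_r2` tibble: `component`, `estimate`, `lower`, `upper`.
#'   Small negative semi-partials are truncated to 0 (with a message).
#' @export
r2_decomposition <- function(fit, predictor_groups = NULL, n_boot = 0,
                             seed = 1) {
  stopifnot(inherits(fit, "troph_fit"))
  if (is.null(predictor_groups)) {
    predictor_groups <- if (fit$type == "drivers") {
      list(range_size = "log10_aoo", intro_year = "intro_year_s",
           proximity = "centroid_dist_s", relatedness = "relatedness")
    } else list()
  }

  full <- troph_r2_point(fit)
  reduced_models <- lapply(predictor_groups, function(v) {
    refit_without(fit, v)
  })
  sp <- vapply(reduced_models, function(m) {
    full[["marginal"]] - lmm_r2(m)[["marginal"]]
  }, numeric(1))
  if (any(sp < 0)) {
    message(sprintf("truncating %d small negative semi-partial(s) to 0",
                    sum(sp < 0)))
    sp <- pmax(sp, 0)
  }

  est <- c(marginal = unname(full[["marginal"]]),
           conditional = unname(full[["conditional"]]), sp)
  out <- tibble::tibble(component = names(est), estimate = unname(est),
                        lower = NA_real_, upper = NA_real_)

  if (n_boot >= 2) {
    sims <- stats::simulate(fit$model, nsim = n_boot, seed = seed)
    boot <- matrix(NA_real_, nrow = n_boot, ncol = length(est))
    for (b in seq_len(n_boot)) {
      y <- sims[[b]]
      mf <- suppressWarnings(lme4::refit(fit$model, y))
      rb <- lmm_r2(mf)
      spb <- vapply(reduced_models, function(m) {
        rb[["marginal"]] - lmm_r2(suppressWarnings(
          lme4::refit(m, y)))[["marginal"]]
      }, numeric(1))
      boot[b, ] <- c(rb[["marginal"]], rb[["conditional"]], pmax(spb, 0))
    }
    out$lower <- apply(boot, 2, quantile, probs = 0.025, na.rm = TRUE)
    out$upper <- apply(boot, 2, quantile, probs = 0.975, na.rm = TRUE)
  }
  class(out) <- c("troph_r2", class(out))
  out
}

troph_r2_point <- function(fit) {
  total <- fit$sigma2_fixed + fit$sigma2_family + fit$sigma2_resid
  c(marginal = fit$sigma2_fixed / total,
    conditional = (fit$sigma2_fixed + fit$sigma2_family) / total)
}

# marginal/conditional R2 of a bare merMod
lmm_r2 <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  s2_fam <- sum(vc$vcov[vc$grp != "Residual"])
  s2_res <- vc$vcov[vc$grp == "Residual"]
  s2_fix <- var(as.vector(model.matrix(model) %*% lme4::fixef(model)))
  total <- s2_fix + s2_fam + s2_res
  c(marginal = s2_fix / total, conditional = (s2_fix + s2_fam) / total)
}

# Refit the model dropping every fixed term that involves `var`
refit_without <- function(fit, var) {
  f <- stats::formula(fit$model)
  fixed_terms <- attr(stats::terms(lme4::nobars(f)), "term.labels")
  keep <- fixed_terms[!grepl(var, fixed_terms, fixed = TRUE)]
  rhs <- if (length(keep) > 0) paste(keep, collapse = " + ") else "1"
  newf <- as.formula(paste(".y ~", rhs, "+ (1 | family)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  lme4::lmer(newf, data = fit$data, REML = TRUE, control = ctrl)
}

#' @export
print.troph_r2 <- function(x, ...) {
  cat("Variance decomposition (R2)\n")
  NextMethod()
  invisible(x)
}
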