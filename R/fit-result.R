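# Shared output contract for the three estimation methods.

# subjects: data.frame(subject, intercept, effect_<condition>...) on the
# absolute scale. beta0/omega2 are named per non-reference condition.
new_fit_result <- function(method, mu0, beta0, tau2, omega2, sigma2,
                           subjects, diagnostics = list()) {
  stopifnot(length(beta0) == length(omega2))
  structure(list(method = method, mu0 = unname(mu0), beta0 = beta0,
                 tau2 = unname(tau2), omega2 = omega2,
                 sigma2 = unname(sigma2), subjects = subjects,
                 diagnostics = diagnostics),
            class = "nof1_fit")
}

#' @export
print.nof1_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d subjects\n", x$method, nrow(x$subjects)))
  cat(sprintf("  mu0   = %.4f   tau = %.4f\n", x$mu0, sqrt(x$tau2)))
  for (k in names(x$beta0)) {
    cat(sprintf("  beta0[%s] = %.4f   omega[%s] = %.4f\n",
                k, x$beta0[[k]], k, sqrt(x$omega2[[k]])))
  }
  cat(sprintf("  sigma = %.4f\n", sqrt(x$sigma2)))
  if (!is.null(x$diagnostics$converged)) {
    cat(sprintf("  converged: %s\n", x$diagnostics$converged))
  }
  invisible(x)
}

#' Flatten a fit to a tidy parameter table
#'
#' One row per population parameter plus one row per subject-level estimate;
#' the serialization used by [write_fit_csv()].
#'
#' @param x A fit returned by [fit_ipd()], [fit_lme_ml()] or
#'   [fit_lme_bayes()].
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data.frame with columns `quantity`, `condition`, `subject`,
#'   `value`.
#' @export
as.data.frame.nof1_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list(data.frame(quantity = "mu0", condition = NA, subject = NA,
                          value = x$mu0),
               data.frame(quantity = "tau2", condition = NA, subject = NA,
                          value = x$tau2),
               data.frame(quantity = "sigma2", condition = NA, subject = NA,
                          value = x$sigma2))
  for (k in names(x$beta0)) {
    rows <- c(rows, list(
      data.frame(quantity = "beta0", condition = k, subject = NA,
                 value = unname(x$beta0[[k]])),
      data.frame(quantity = "omega2", condition = k, subject = NA,
                 value = unname(x$omega2[[k]]))))
  }
  s <- x$subjects
  rows <- c(rows, list(
    data.frame(quantity = "intercept_i", condition = NA, subject = s$subject,
               value = s$intercept)))
  for (k in names(x$beta0)) {
    col <- paste0("effect_", k)
    if (col %in% names(s)) {
      rows <- c(rows, list(
        data.frame(quantity = "beta_i", condition = k, subject = s$subject,
                   value = s[[col]])))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a fit to a flat CSV
#'
#' @param fit A fit object (class `nof1_fit`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  utils::write.csv(as.data.frame(fit), path, row.names = FALSE, na = "")
  invisible(path)
}
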