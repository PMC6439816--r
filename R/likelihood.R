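# Joint categorical/continuous pair likelihood.
#
# For one twin pair the model says (trait1, liab1, trait2, liab2) is
# multivariate normal with the correlation matrix implied by the parameters,
# and an observed diagnosis indicates liability above the sex-specific
# threshold. The likelihood of a (possibly partially missing) observation
# factorises exactly: density of the observed continuous components times
# the conditional-normal rectangle probability of the observed binary
# components. Missing elements are marginalised by dropping their rows.

# loglik of all pairs in one missingness group sharing matrix R.
# g: list(idx, ot = c(obs t1, obs t2), oy = c(obs y1, obs y2)).
# tauv = c(tau_M, tau_F); d carries i1/i2 = 1 (M) or 2 (F).
.group_loglik <- function(R, d, g, tauv, log_sd_t = 0) {
  idx <- g$idx
  ti <- c(1, 3)[g$ot]
  li <- c(2, 4)[g$oy]
  v <- numeric(length(idx))
  t1 <- d$t1[idx]; t2 <- d$t2[idx]
  if (length(ti) == 2L) {
    r <- R[1, 3]
    q <- (t1^2 - 2 * r * t1 * t2 + t2^2) / (1 - r^2)
    v <- v - log(2 * pi) - 0.5 * log(1 - r^2) - q / 2 - 2 * log_sd_t
  } else if (length(ti) == 1L) {
    tv <- if (g$ot[1]) t1 else t2
    v <- v + dnorm(tv, log = TRUE) - log_sd_t
  }
  if (length(li) > 0L) {
    if (length(ti) > 0L) {
      A <- R[li, ti, drop = FALSE] %*% solve(R[ti, ti, drop = FALSE])
      Tm <- cbind(if (g$ot[1]) t1, if (g$ot[2]) t2)
      mu <- Tm %*% t(A)
      Sc <- R[li, li, drop = FALSE] - A %*% t(R[li, ti, drop = FALSE])
    } else {
      mu <- matrix(0, length(idx), length(li))
      Sc <- R[li, li, drop = FALSE]
    }
    sdc <- sqrt(pmax(diag(Sc), 1e-12))
    tau12 <- cbind(tauv[d$i1[idx]], tauv[d$i2[idx]])[, g$oy, drop = FALSE]
    yo <- cbind(d$y1[idx], d$y2[idx])[, g$oy, drop = FALSE]
    u <- sweep(tau12 - mu, 2, sdc, "/")
    s <- 1 - 2 * yo
    if (length(li) == 2L) {
      rho_c <- max(min(Sc[1, 2] / (sdc[1] * sdc[2]), 1), -1)
      v <- v + log_rect2(u[, 1], u[, 2], s[, 1], s[, 2], rho_c)
    } else {
      v <- v + pnorm(s[, 1] * u[, 1], log.p = TRUE)
    }
  }
  v
}

# missingness pattern groups for one class worth of wide data
.make_groups <- function(d) {
  pat <- (!is.na(d$t1)) + 2L * (!is.na(d$t2)) + 4L * (!is.na(d$y1)) +
    8L * (!is.na(d$y2))
  lapply(sort(unique(pat)), function(p) {
    list(idx = which(pat == p),
         ot = c(bitwAnd(p, 1L) > 0, bitwAnd(p, 2L) > 0),
         oy = c(bitwAnd(p, 4L) > 0, bitwAnd(p, 8L) > 0))
  })
}

.class_loglik <- function(R, d, tauv, log_sd_t = 0) {
  sum(vapply(d$groups, function(g)
    sum(.group_loglik(R, d, g, tauv, log_sd_t)), 0))
}

#' Exact log-likelihood of one twin pair under a bivariate twin model
#'
#' Computes the joint log-likelihood of a single pair's observed data
#' (continuous trait values and binary diagnoses, either of which may be
#' missing for either twin) under the model implied by a [twin_spec()]:
#' multivariate-normal density for the observed continuous components times
#' the conditional bivariate-normal rectangle probability for the observed
#' diagnoses, with sex-specific thresholds taken from the spec.
#'
#' @param spec a [twin_spec()] holding the model parameters
#' @param zygosity `"MZ"` or `"DZ"`
#' @param trait length-2 numeric `(twin1, twin2)`, `NA` allowed
#' @param diagnosis length-2 0/1, `NA` allowed
#' @param sex length-2 `"M"`/`"F"`
#' @return scalar log-likelihood (`-Inf` if the parameters imply a
#'   non-positive-definite covariance)
#' @export
joint_pair_loglik <- function(spec, zygosity, trait, diagnosis,
                              sex = c("M", "M")) {
  R <- tryCatch(cov2cor(implied_moments(spec, zygosity)),
                error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  if (all(is.na(trait)) && all(is.na(diagnosis))) return(0)
  d <- list(t1 = trait[1], t2 = trait[2],
            y1 = as.integer(diagnosis[1]), y2 = as.integer(diagnosis[2]),
            i1 = 1L + (sex[1] == "F"), i2 = 1L + (sex[2] == "F"))
  g <- list(idx = 1L, ot = !is.na(trait), oy = !is.na(diagnosis))
  unname(.group_loglik(R, d, g, c(spec$tau[["M"]], spec$tau[["F"]])))
}

# Split a phenotype table into per-zygosity-class wide arrays used by the
# fitter. MZ pools MZM+MZF; DZ pools DZM+DZF+DZOS (no sex-limitation model;
# sex enters only through thresholds). Pairs with no observed data drop out.
.fit_data <- function(pairs, trait, diagnosis) {
  w <- pair_wide(pairs, c(trait, diagnosis))
  zclass <- ifelse(w$zygosity %in% c("MZM", "MZF"), "MZ", "DZ")
  out <- list()
  for (z in c("MZ", "DZ")) {
    d0 <- w[zclass == z, , drop = FALSE]
    if (!nrow(d0)) next
    t1 <- d0[[paste0(trait, ".1")]]; t2 <- d0[[paste0(trait, ".2")]]
    y1 <- d0[[paste0(diagnosis, ".1")]]; y2 <- d0[[paste0(diagnosis, ".2")]]
    keep <- !(is.na(t1) & is.na(t2) & is.na(y1) & is.na(y2))
    d <- list(t1 = t1[keep], t2 = t2[keep], y1 = y1[keep], y2 = y2[keep],
              i1 = 1L + (d0$sex.1[keep] == "F"),
              i2 = 1L + (d0$sex.2[keep] == "F"),
              n = sum(keep))
    d$groups <- .make_groups(d)
    out[[z]] <- d
  }
  out
}
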