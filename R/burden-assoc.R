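.check_phenotype <- function(phenotype, samples = NULL) {
  stopifnot(is.data.frame(phenotype),
            all(c("sample", "status") %in% names(phenotype)))
  if (!all(phenotype$status %in% c("case", "control")))
    stop("phenotype status must be 'case' or 'control'", call. = FALSE)
  if (!is.null(samples)) {
    m <- match(samples, phenotype$sample)
    if (anyNA(m))
      stop("phenotype missing sample(s): ",
           paste(utils::head(samples[is.na(m)], 5), collapse = ", "),
           call. = FALSE)
    phenotype <- phenotype[m, , drop = FALSE]
  }
  if (!any(phenotype$status == "case") || !any(phenotype$status == "control"))
    stop("phenotype must contain at least one case and one control",
         call. = FALSE)
  phenotype
}

#' Collapse per-gene burdens to a 2x2 carrier table
#'
#' A sample is a carrier of a gene when its max-weight burden exceeds
#' `tau` (default 0: any positively weighted qualifying variant).
#'
#' @param burden Samples x genes burden matrix from
#'   [compute_gene_burden()].
#' @param phenotype data.frame with columns `sample`, `status`
#'   (`case`/`control`).
#' @param gene Gene identifier (a column of `burden`).
#' @param tau Carrier threshold on the burden value.
#' @return Named integer vector `(case_carriers, case_noncarriers,
#'   control_carriers, control_noncarriers)`.
#' @export
collapse_carriers <- function(burden, phenotype, gene, tau = 0) {
  if (!gene %in% colnames(burden))
    stop("collapse_carriers: gene '", gene, "' not in burden matrix",
         call. = FALSE)
  ph <- .check_phenotype(phenotype, rownames(burden))
  carrier <- burden[, gene] > tau
  is_case <- ph$status == "case"
  c(case_carriers = sum(carrier & is_case),
    case_noncarriers = sum(!carrier & is_case),
    control_carriers = sum(carrier & !is_case),
    control_noncarriers = sum(!carrier & !is_case))
}

#' Odds ratio and two-sided exact p for a 2x2 carrier table
#'
#' The odds ratio is the cross-product `(a*d)/(b*c)` for the table
#' `(a, b, c, d)` = (case carriers, case non-carriers, control
#' carriers, control non-carriers); when any cell is 0 the
#' Haldane-Anscombe +0.5 correction is applied to every cell and the
#' result is flagged `corrected`. The p-value is the standard two-sided
#' exact test obtained by enumerating hypergeometric tables at the
#' observed margins ([stats::fisher.test()]). A table with an all-zero
#' carrier (or non-carrier) margin has no defined odds ratio: `NA` is
#' returned with a note, and p = 1.
#'
#' @param counts Length-4 vector `(a, b, c, d)` as above, or a 2x2
#'   matrix `rbind(c(a, b), c(c, d))`.
#' @return List with `odds_ratio`, `p_value`, `corrected` (logical) and
#'   `note`.
#' @examples
#' fisher_or(c(10, 401, 5, 3795))$odds_ratio # 18.93
#' @export
fisher_or <- function(counts) {
  x <- as.vector(t(counts))
  stopifnot(length(x) == 4, all(x >= 0), all(x == round(x)))
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  tab <- matrix(c(a, cc, b, d), 2)
  if (a + cc == 0 || b + d == 0 || a + b == 0 || cc + d == 0) {
    p <- if (sum(x) == 0) NA_real_ else 1
    return(list(odds_ratio = NA_real_, p_value = p, corrected = FALSE,
                note = "zero margin: odds ratio undefined"))
  }
  p <- stats::fisher.test(tab)$p.value
  if (any(x == 0)) {
    or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5))
    list(odds_ratio = or, p_value = min(p, 1), corrected = TRUE,
         note = "Haldane-Anscombe +0.5 applied")
  } else {
    list(odds_ratio = a * d / (b * cc), p_value = min(p, 1),
         corrected = FALSE, note = "")
  }
}

#' Permutation p-value for a gene's burden
#'
#' Statistic: mean burden in cases minus mean burden in controls.
#' Case/control labels are permuted `n_perm` times and the one-sided
#' add-one estimate `p = (1 + #{permuted >= observed}) / (n_perm + 1)`
#' is returned, honouring the `1/(n_perm + 1)` lower bound.
#'
#' @param burden Numeric burden values, one per sample.
#' @param status Character `case`/`control` (or 0/1) labels aligned with
#'   `burden`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional seed for reproducible permutations.
#' @return Permutation p-value.
#' @export
permutation_p <- function(burden, status, n_perm = 1000, seed = NULL) {
  stopifnot(length(burden) == length(status), n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  y <- .as_case_indicator(status)
  n1 <- sum(y); n0 <- length(y) - n1
  stopifnot(n1 >= 1, n0 >= 1)
  tot <- sum(burden)
  stat <- function(s1) s1 / n1 - (tot - s1) / n0
  obs <- stat(sum(burden[y == 1]))
  n <- length(burden)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    s1 <- sum(burden[sample.int(n, n1)])
    if (stat(s1) >= obs - 1e-12) ge <- ge + 1L
  }
  (1 + ge) / (n_perm + 1)
}

.as_case_indicator <- function(status) {
  if (is.numeric(status)) {
    stopifnot(all(status %in% c(0, 1)))
    as.integer(status)
  } else {
    stopifnot(all(status %in% c("case", "control")))
    as.integer(status == "case")
  }
}

#' Logistic score test of a gene's burden
#'
#' Score test of the burden coefficient in a logistic regression of
#' case status on burden plus optional numeric covariates: the null
#' model (covariates only) is fitted by maximum likelihood and the
#' efficient score for the burden term is compared with chi-squared(1).
#' Effect size (`beta`, `se`) comes from the full-model fit; when
#' separation is detected there, a Firth-penalised fit is substituted
#' and its Wald p reported. With fewer than 10 carriers the asymptotic
#' test is unreliable and the function falls back to [permutation_p()].
#' A burden with zero variance is untestable and returns a missing p
#' with a reason.
#'
#' @param burden Numeric burden values, one per sample.
#' @param status Character `case`/`control` (or 0/1) labels.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param n_perm Permutations for the low-carrier fallback.
#' @param seed Seed for the permutation fallback.
#' @return List with `beta`, `se`, `p`, `method`
#'   (`"score"`/`"firth"`/`"permutation"`/`"none"`), `n_carriers` and
#'   `reason`.
#' @export
logistic_burden_test <- function(burden, status, covariates = NULL,
                                 n_perm = 2000, seed = NULL) {
  y <- .as_case_indicator(status)
  stopifnot(length(burden) == length(y), sum(y) >= 1, sum(1 - y) >= 1)
  if (stats::var(burden) == 0)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                method = "none", n_carriers = sum(burden > 0),
                reason = "zero burden variance"))
  n_carriers <- sum(burden > 0)
  if (n_carriers < 10) {
    p <- permutation_p(burden, y, n_perm = n_perm, seed = seed)
    return(list(beta = NA_real_, se = NA_real_, p = p,
                method = "permutation", n_carriers = n_carriers,
                reason = "carrier count < 10"))
  }
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(y), is.numeric(covariates))
    X <- cbind(X, covariates)
  }
  fit0 <- stats::glm.fit(X, y, family = stats::binomial())
  mu <- fit0$fitted.values
  Wv <- mu * (1 - mu)
  U <- sum(burden * (y - mu))
  XtWX <- crossprod(X * Wv, X)
  XtWg <- crossprod(X * Wv, burden)
  V <- sum(burden^2 * Wv) - drop(crossprod(XtWg, solve(XtWX, XtWg)))
  if (V <= 0)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                method = "none", n_carriers = n_carriers,
                reason = "degenerate score variance"))
  p_score <- stats::pchisq(U^2 / V, df = 1, lower.tail = FALSE)

  Xf <- cbind(burden = burden, X)
  fit1 <- suppressWarnings(stats::glm.fit(Xf, y, family = stats::binomial()))
  separated <- !fit1$converged || any(abs(fit1$coefficients) > 15) ||
    any(fit1$fitted.values > 1 - 1e-10 & y == 0) ||
    any(fit1$fitted.values < 1e-10 & y == 1)
  if (separated) {
    fr <- .firth_logistic(Xf, y)
    z <- fr$coef[1] / fr$se[1]
    list(beta = fr$coef[1], se = fr$se[1],
         p = 2 * stats::pnorm(-abs(z)), method = "firth",
         n_carriers = n_carriers, reason = "separation detected")
  } else {
    se <- sqrt(diag(solve(crossprod(
      Xf * fit1$fitted.values * (1 - fit1$fitted.values), Xf))))[1]
    list(beta = unname(fit1$coefficients[1]), se = unname(se),
         p = p_score, method = "score", n_carriers = n_carriers,
         reason = "")
  }
}

# Firth-penalised logistic regression (Jeffreys-prior score correction),
# plain IRLS with step capping; enough for the separation fallback.
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    Wv <- mu * (1 - mu)
    info <- crossprod(X * Wv, X)
    inv <- solve(info)
    h <- rowSums((X %*% inv) * X) * Wv
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- drop(inv %*% U)
    delta <- pmin(pmax(delta, -5), 5)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  list(coef = beta, se = sqrt(diag(inv)))
}

#' Scan a candidate-gene panel for burden association
#'
#' Per gene: collapse carriers at threshold `tau` and run the exact
#' collapsing test ([fisher_or()]); optionally add the logistic score
#' test and/or the permutation test. Results carry nominal p-values
#' (primary: collapsing test) plus Benjamini-Hochberg q-values, sorted
#' ascending by p. Deterministic for a given `seed`.
#'
#' @param burden Samples x genes burden matrix.
#' @param phenotype data.frame `sample`, `status`.
#' @param methods Subset of `c("fisher", "logistic", "permutation")`.
#' @param tau Carrier threshold (see [collapse_carriers()]).
#' @param covariates Optional covariates for the logistic engine.
#' @param n_perm Permutations for the permutation engine.
#' @param seed Integer seed controlling permutation draws.
#' @param compute_q Add Benjamini-Hochberg q-values (default TRUE).
#' @return data.frame with one row per gene: `gene_id`,
#'   `n_case_carriers`, `n_control_carriers`, `odds_ratio`,
#'   `or_corrected`, `p_fisher`, `p_score`, `p_perm`, `q_bh`.
#' @export
run_gene_scan <- function(burden, phenotype,
                          methods = "fisher", tau = 0,
                          covariates = NULL, n_perm = 1000, seed = 1L,
                          compute_q = TRUE) {
  methods <- match.arg(methods, c("fisher", "logistic", "permutation"),
                       several.ok = TRUE)
  genes <- colnames(burden)
  if (is.null(genes) || length(genes) == 0) {
    out <- data.frame(gene_id = character(), n_case_carriers = integer(),
                      n_control_carriers = integer(), odds_ratio = numeric(),
                      or_corrected = logical(), p_fisher = numeric(),
                      p_score = numeric(), p_perm = numeric(),
                      q_bh = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  ph <- .check_phenotype(phenotype, rownames(burden))
  y <- .as_case_indicator(ph$status)
  set.seed(seed)
  rows <- lapply(genes, function(g) {
    tab <- collapse_carriers(burden, ph, g, tau = tau)
    ft <- fisher_or(tab)
    p_score <- NA_real_
    if ("logistic" %in% methods) {
      lt <- logistic_burden_test(burden[, g], y, covariates = covariates,
                                 n_perm = n_perm)
      p_score <- lt$p
    }
    p_perm <- if ("permutation" %in% methods)
      permutation_p(burden[, g], y, n_perm = n_perm) else NA_real_
    data.frame(gene_id = g,
               n_case_carriers = unname(tab["case_carriers"]),
               n_control_carriers = unname(tab["control_carriers"]),
               odds_ratio = ft$odds_ratio,
               or_corrected = ft$corrected,
               p_fisher = ft$p_value,
               p_score = p_score, p_perm = p_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- if (compute_q) stats::p.adjust(out$p_fisher, "BH") else NA_real_
  out <- out[order(out$p_fisher, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
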