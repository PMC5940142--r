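# Mixed-model machinery for the response-surface scan.
#
# The observation covariance is V = sigma_l^2 Z K Z' + sigma_e^2 I with Z the
# line incidence matrix. Z K Z' has rank at most the number of lines, so its
# spectrum is obtained from the thin SVD of G = Z chol(K)': all whitening,
# determinant and GLS operations then cost O(n * q) per evaluation instead of
# O(n^3), which keeps the REML profile and the per-marker scan fast.

build_vstruct <- function(line_id, kmat) {
  lines <- sort(unique(line_id))
  if (!all(lines %in% rownames(kmat))) {
    abort("some phenotype lines are absent from the kinship matrix.",
          class = "surfqtl_invalid_argument")
  }
  K <- unclass(kmat)[lines, lines, drop = FALSE]
  L <- tryCatch(t(chol(K)), error = function(e) {
    abort("kinship matrix is not positive semi-definite.",
          class = "surfqtl_model_specification")
  })
  G <- L[match(line_id, lines), , drop = FALSE]
  sv <- svd(G, nu = min(dim(G)), nv = 0)
  list(U = sv$u, d2 = sv$d^2, n = length(line_id))
}

# H^{-1/2} M for H = I + lambda Z K Z'
whiten_H <- function(vs, M, lambda) {
  M <- as.matrix(M)
  if (lambda == 0) return(M)
  s <- 1 - 1 / sqrt(1 + lambda * vs$d2)
  M - vs$U %*% (s * crossprod(vs$U, M))
}

# profile REML over the variance ratio lambda = sigma_l^2 / sigma_e^2
reml_variance_components <- function(y, X, vs) {
  n <- length(y); p <- ncol(X)
  crit <- function(loglam) {
    lam <- exp(loglam)
    Xw <- whiten_H(vs, X, lam)
    yw <- whiten_H(vs, y, lam)
    qr0 <- qr(Xw)
    rss <- sum(qr.resid(qr0, yw)^2)
    ldH <- sum(log1p(lam * vs$d2))
    ldXX <- 2 * sum(log(abs(diag(qr.R(qr0)))))
    (n - p) * log(rss) + ldH + ldXX
  }
  lo <- log(1e-8); hi <- log(1e8)
  opt <- optimize(crit, c(lo, hi))
  # allow the boundary solution sigma_l^2 = 0 exactly
  loglam <- if (crit(lo) <= opt$objective) -Inf else opt$minimum
  lam <- if (is.finite(loglam)) exp(loglam) else 0
  Xw <- whiten_H(vs, X, lam)
  yw <- whiten_H(vs, y, lam)
  rss <- sum(qr.resid(qr(Xw), yw)^2)
  sigma_e2 <- rss / (n - p)
  c(sigma2_line = lam * sigma_e2, sigma2_resid = sigma_e2)
}

surface_design_matrix <- function(ph) {
  cbind(ell = 1, beta1 = ph$xw, beta2 = ph$xn, beta3 = ph$xw^2,
        beta4 = ph$xn^2, beta5 = ph$xw * ph$xn)
}

coef_row <- function(b) {
  tibble::tibble(beta1 = b[["beta1"]], beta2 = b[["beta2"]],
                 beta3 = b[["beta3"]], beta4 = b[["beta4"]],
                 beta5 = b[["beta5"]], ell = b[["ell"]])
}

#' Fit the quadratic surface mixed model
#'
#' Fits the growth surface with a kinship-structured random line effect.
#' Variance components (`sigma2_line`, `sigma2_resid`) are estimated by
#' profile REML on the all-inclusive (single-surface) model; fixed
#' coefficients are then estimated by generalised least squares under the
#' implied covariance. With `marker` given, lines missing a call there are
#' dropped and one six-coefficient set is estimated per allele group under
#' the same covariance (a single 12-column GLS, so the nesting against the
#' all-inclusive fit on the same records is exact).
#'
#' @param phenotypes A `phenotype_table` (needs `line_id`, `xw`, `xn`,
#'   `diff_height_cm`).
#' @param kinship Optional `kinship_matrix`; identity relatedness if NULL.
#' @param genotypes A `genotype_matrix`; required when `marker` is given.
#' @param marker Optional marker id to split the fit by allele.
#' @param vc Optional pre-estimated variance components
#'   `c(sigma2_line, sigma2_resid)`; when supplied REML is skipped (the scan
#'   estimates them once on the all-inclusive model and reuses them so RSS
#'   values stay comparable).
#' @return A `surface_fit`: coefficients (one row per group), variance
#'   components, whitened residual sum of squares, and bookkeeping.
#' @examples
#' g <- simulate_genotypes(20, tibble::tibble(n_markers = 3, length_cm = 50), seed = 1)
#' ph <- simulate_phenotypes(g, sigma_line = 0, sigma_resid = 1, seed = 2)
#' fit_surface(ph)
#' @export
fit_surface <- function(phenotypes, kinship = NULL, genotypes = NULL,
                        marker = NULL, vc = NULL) {
  ph <- tibble::as_tibble(phenotypes)
  needed <- c("line_id", "xw", "xn", "diff_height_cm")
  if (!all(needed %in% names(ph))) {
    abort("phenotypes need columns line_id, xw, xn, diff_height_cm.",
          class = "surfqtl_format_error")
  }
  group <- NULL
  if (!is.null(marker)) {
    if (is.null(genotypes)) {
      abort("`genotypes` is required when `marker` is given.",
            class = "surfqtl_invalid_argument")
    }
    calls <- genotypes$calls[, marker]
    ph$call <- calls[ph$line_id]
    ph <- ph[!is.na(ph$call), ]
    group <- factor(ph$call, levels = c("B73", "Mo17"))
    if (nlevels(droplevels(group)) < 2) {
      abort("marker is monomorphic on the phenotyped lines.",
            class = "surfqtl_rank_deficiency")
    }
  }
  lines <- unique(ph$line_id)
  kmat <- if (is.null(kinship)) {
    k <- diag(length(lines)); dimnames(k) <- list(lines, lines); k
  } else {
    kinship
  }
  vs <- build_vstruct(ph$line_id, kmat)
  X0 <- surface_design_matrix(ph)
  y <- ph$diff_height_cm
  if (is.null(vc)) vc <- reml_variance_components(y, X0, vs)
  lam <- if (vc[["sigma2_resid"]] > 0) vc[["sigma2_line"]] / vc[["sigma2_resid"]] else 0

  X <- if (is.null(group)) X0 else {
    XB <- X0 * (group == "B73")
    XM <- X0 * (group == "Mo17")
    colnames(XB) <- paste0(colnames(X0), "_B73")
    colnames(XM) <- paste0(colnames(X0), "_Mo17")
    cbind(XB, XM)
  }
  p <- ncol(X)
  if (nrow(X) <= p) {
    abort("more fixed parameters than observations.",
          class = "surfqtl_rank_deficiency")
  }
  Xw <- whiten_H(vs, X, lam)
  yw <- whiten_H(vs, y, lam)
  qrx <- qr(Xw)
  if (qrx$rank < p) {
    abort("singular design: the stress levels do not support a quadratic surface fit.",
          class = "surfqtl_rank_deficiency")
  }
  beta <- qr.coef(qrx, yw)[, 1]
  # correlation-whitened residual sum of squares; the residual variance scale
  # cancels in the scan's F ratio so it is left unscaled (and is ~0 for a
  # noiseless model-generated fit)
  weighted_rss <- sum(qr.resid(qrx, yw)^2)

  coefs <- if (is.null(group)) {
    dplyr::bind_cols(tibble::tibble(group = "all"), coef_row(beta))
  } else {
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(group = "B73"),
                       coef_row(setNames(beta[1:6], colnames(X0)))),
      dplyr::bind_cols(tibble::tibble(group = "Mo17"),
                       coef_row(setNames(beta[7:12], colnames(X0))))
    )
  }
  structure(
    list(coefficients = coefs, vc = vc, weighted_rss = weighted_rss,
         n_obs = nrow(X), n_fixed = p, marker = marker, lines = lines),
    class = "surface_fit"
  )
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("<surface_fit> %d obs, %d fixed params, weighted RSS %.4g\n",
              x$n_obs, x$n_fixed, x$weighted_rss))
  cat(sprintf("  sigma2_line = %.4g, sigma2_resid = %.4g\n",
              x$vc[["sigma2_line"]], x$vc[["sigma2_resid"]]))
  print(x$coefficients)
  invisible(x)
}

#' Per-marker response-surface F-scan
#'
#' For each marker, compares the two-allele surface model (separate
#' six-coefficient sets per allele group) against the all-inclusive single
#' surface on the same records via
#' \deqn{F = \frac{(RSS_0 - RSS_1)/6}{RSS_1/(n - 12)},}
#' with RSS values whitened under the covariance implied by the REML
#' variance components estimated once on the all-inclusive model. Lines
#' missing a call at a marker are dropped for that marker only and the
#' all-inclusive RSS is recomputed on the reduced records. Markers whose
#' minor allele class has fewer than `min_class` observations are skipped
#' and flagged.
#'
#' @param phenotypes A `phenotype_table`.
#' @param genotypes A `genotype_matrix`.
#' @param kinship Optional `kinship_matrix`.
#' @param min_class Minimum observations in the smaller allele class
#'   (default 10).
#' @param vc Optional variance components to reuse.
#' @return A `scan_result` tibble: per marker `marker_id`, `chrom`,
#'   `order`, `pos_cm`, `n_obs`, `F`, `raw_p`, `skipped`; variance
#'   components in `attr(, "vc")`.
#' @export
marker_scan <- function(phenotypes, genotypes, kinship = NULL,
                        min_class = 10, vc = NULL) {
  ph <- tibble::as_tibble(phenotypes)
  shared <- intersect(unique(ph$line_id), genotypes$line_ids)
  if (length(shared) == 0) {
    abort("no shared line ids between phenotypes and genotypes.",
          class = "surfqtl_invalid_argument")
  }
  ph <- ph[ph$line_id %in% shared, ]
  lines <- unique(ph$line_id)
  kmat <- if (is.null(kinship)) {
    k <- diag(length(lines)); dimnames(k) <- list(lines, lines); k
  } else {
    kinship
  }
  vs_full <- build_vstruct(ph$line_id, kmat)
  X0 <- surface_design_matrix(ph)
  y <- ph$diff_height_cm
  if (is.null(vc)) vc <- reml_variance_components(y, X0, vs_full)
  lam <- if (vc[["sigma2_resid"]] > 0) vc[["sigma2_line"]] / vc[["sigma2_resid"]] else 0
  Xw_full <- whiten_H(vs_full, X0, lam)
  yw_full <- whiten_H(vs_full, y, lam)
  rss0_full <- sum(qr.resid(qr(Xw_full), yw_full)^2)

  map <- dplyr::arrange(genotypes$map, .data$chrom, .data$pos_cm)
  scan_one <- function(mk) {
    call_at <- genotypes$calls[ph$line_id, mk]
    keep <- !is.na(call_at)
    nB <- sum(call_at[keep] == "B73")
    nM <- sum(call_at[keep] == "Mo17")
    n <- nB + nM
    if (min(nB, nM) < min_class || n <= 12) {
      return(tibble::tibble(n_obs = n, F = NA_real_, raw_p = NA_real_,
                            skipped = TRUE))
    }
    grp <- call_at[keep]
    if (all(keep)) {
      Xw0 <- Xw_full; yw <- yw_full; rss0 <- rss0_full
      Xw1 <- whiten_H(vs_full, cbind(X0 * (grp == "B73"), X0 * (grp == "Mo17")), lam)
    } else {
      vs <- build_vstruct(ph$line_id[keep], kmat)
      Xs <- X0[keep, , drop = FALSE]
      Xw0 <- whiten_H(vs, Xs, lam)
      yw <- whiten_H(vs, y[keep], lam)
      rss0 <- sum(qr.resid(qr(Xw0), yw)^2)
      Xw1 <- whiten_H(vs, cbind(Xs * (grp == "B73"), Xs * (grp == "Mo17")), lam)
    }
    rss1 <- sum(qr.resid(qr(Xw1), yw)^2)
    num <- max(rss0 - rss1, 0)
    # identical fits (e.g. noiseless data with no allele difference) give
    # 0/0; the model comparison carries no evidence, so F = 0
    Fstat <- if (num <= 1e-10 * max(rss0, 1)) 0 else (num / 6) / (rss1 / (n - 12))
    tibble::tibble(n_obs = n, F = Fstat,
                   raw_p = pf(Fstat, 6, n - 12, lower.tail = FALSE),
                   skipped = FALSE)
  }
  res <- purrr::map_dfr(map$marker_id, scan_one)
  out <- dplyr::bind_cols(
    tibble::tibble(marker_id = map$marker_id, chrom = map$chrom,
                   pos_cm = map$pos_cm,
                   order = stats::ave(seq_len(nrow(map)), map$chrom,
                                      FUN = seq_along)),
    res
  )
  if (all(out$skipped)) {
    abort("no scannable markers.", class = "surfqtl_empty_scan")
  }
  structure(out, class = c("scan_result", class(out)), vc = vc)
}

#' Simes smoothing of a marker scan
#'
#' Replaces each marker's p-value with the Simes combination of the window
#' of up to `window` map-adjacent scanned markers centred on it (truncated
#' at chromosome ends, never spanning chromosomes): for the sorted window
#' p-values \eqn{p_{(1)} \le \dots \le p_{(w)}}, the smoothed value is
#' \eqn{\min_k w\,p_{(k)}/k}, capped at 1. Skipped markers contribute
#' nothing and receive no smoothed value.
#'
#' @param scan A `scan_result`.
#' @param window Odd window size (default 5).
#' @return The scan with a `smoothed_p` column added.
#' @export
simes_smooth <- function(scan, window = 5) {
  stopifnot(inherits(scan, "scan_result"))
  if (window %% 2 != 1 || window < 1) {
    abort("`window` must be a positive odd integer.",
          class = "surfqtl_invalid_argument")
  }
  half <- (window - 1) / 2
  out <- scan
  out$smoothed_p <- NA_real_
  for (ch in unique(scan$chrom)) {
    idx <- which(scan$chrom == ch & !scan$skipped)
    if (is.unsorted(scan$pos_cm[idx])) {
      abort("markers must be map-ordered within chromosome.",
            class = "surfqtl_invalid_argument")
    }
    m <- length(idx)
    for (i in seq_len(m)) {
      win <- idx[max(1, i - half):min(m, i + half)]
      p <- sort(scan$raw_p[win])
      w <- length(p)
      out$smoothed_p[idx[i]] <- min(1, min(w * p / seq_len(w)))
    }
  }
  out
}

#' Sidak experiment-wise threshold
#'
#' @param m Number of tests.
#' @param alpha Experiment-wise error rate in (0, 1).
#' @return The per-test threshold \eqn{1 - (1-\alpha)^{1/m}}.
#' @export
sidak_threshold <- function(m, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "surfqtl_invalid_argument")
  }
  if (m < 1) abort("`m` must be >= 1.", class = "surfqtl_invalid_argument")
  1 - (1 - alpha)^(1 / m)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values, or the Sidak experiment-wise
#' rule (per-test threshold plus significance flags).
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param method `"BH"` or `"sidak"`.
#' @param alpha Error rate for the Sidak rule.
#' @return For `"BH"`, the adjusted p-values; for `"sidak"`, a list with
#'   `threshold` and logical `significant`.
#' @examples
#' adjust_pvalues(c(0.01, 0.04, 0.03), "BH")
#' adjust_pvalues(c(0.01, 0.04, 0.03), "sidak", alpha = 0.05)
#' @export
adjust_pvalues <- function(p, method = c("BH", "sidak"), alpha = 0.05) {
  method <- match.arg(method)
  ok <- p[!is.na(p)]
  if (length(ok) < 1 || any(ok < 0 | ok > 1)) {
    abort("p-values must lie in [0, 1].", class = "surfqtl_invalid_argument")
  }
  if (method == "BH") {
    p.adjust(p, method = "BH")
  } else {
    thr <- sidak_threshold(sum(!is.na(p)), alpha)
    list(threshold = thr, significant = !is.na(p) & p < thr)
  }
}

#' Annotate a smoothed scan with adjusted significance
#'
#' Adds BH-FDR adjusted values (`fdr_p`) and Sidak flags (`sidak_sig`)
#' computed on the smoothed p-values.
#'
#' @param scan A `scan_result` with `smoothed_p` (run [simes_smooth()]
#'   first; it is applied with the default window if absent).
#' @param alpha Error rate for the Sidak rule.
#' @return The scan with `fdr_p` and `sidak_sig` columns.
#' @export
adjust_scan <- function(scan, alpha = 0.05) {
  stopifnot(inherits(scan, "scan_result"))
  if (is.null(scan[["smoothed_p"]])) scan <- simes_smooth(scan)
  out <- scan
  out$fdr_p <- adjust_pvalues(scan$smoothed_p, "BH")
  sid <- adjust_pvalues(scan$smoothed_p, "sidak", alpha)
  out$sidak_sig <- sid$significant
  attr(out, "sidak_threshold") <- sid$threshold
  out
}

#' Call QTL intervals from a smoothed, adjusted scan
#'
#' Merges maximal runs of map-adjacent significant markers (singletons
#' allowed) into intervals, one per run, reporting the bounding markers and
#' the minimum-p marker.
#'
#' @param scan A `scan_result`; [simes_smooth()] and [adjust_scan()] are
#'   applied with defaults if their columns are absent.
#' @param criterion `"sidak"` (experiment-wise) or `"fdr"`.
#' @param alpha Significance level (default 0.05).
#' @return A tibble of intervals: `chrom`, `start_marker`, `end_marker`,
#'   `best_marker`, `best_p`, `n_markers`.
#' @export
call_qtl <- function(scan, criterion = c("sidak", "fdr"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(scan, "scan_result"))
  if (is.null(scan[["smoothed_p"]])) scan <- simes_smooth(scan)
  if (is.null(scan[["fdr_p"]]) || is.null(scan[["sidak_sig"]])) {
    scan <- adjust_scan(scan, alpha)
  }
  sig <- if (criterion == "sidak") {
    !is.na(scan$sidak_sig) & scan$sidak_sig
  } else {
    !is.na(scan$fdr_p) & scan$fdr_p <= alpha
  }
  out <- list()
  for (ch in unique(scan$chrom)) {
    idx <- which(scan$chrom == ch & !scan$skipped)
    if (!length(idx)) next
    flags <- sig[idx]
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run <- idx[starts[k]:ends[k]]
      best <- run[which.min(scan$smoothed_p[run])]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch,
        start_marker = scan$marker_id[run[1]],
        end_marker = scan$marker_id[run[length(run)]],
        best_marker = scan$marker_id[best],
        best_p = scan$smoothed_p[best],
        n_markers = length(run)
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = integer(), start_marker = character(),
                          end_marker = character(), best_marker = character(),
                          best_p = double(), n_markers = integer()))
  }
  dplyr::bind_rows(out)
}
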