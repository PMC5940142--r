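#' Simulate a biparental recombinant-inbred genotype matrix
#'
#' Emulates a fully homozygous intermated RIL population (B73 x Mo17).
#' Along each chromosome, alleles follow a two-state Markov chain whose
#' switch probability between adjacent markers is the Haldane recombination
#' fraction for the map distance multiplied by `expansion_factor`
#' (intermating expands the effective map; a scalar factor reproduces the
#' marker autocorrelation structure the downstream scan sees). Chromosomes
#' are independent; the first marker of each chromosome is a fair draw.
#'
#' @param n_lines Number of lines (>= 2).
#' @param chromosomes Data frame with one row per chromosome and columns
#'   `n_markers` (>= 2) and `length_cm`, or NULL for the default 10
#'   chromosomes of 20 equally spaced markers over 120 cM.
#' @param expansion_factor Map-expansion multiplier (default 4).
#' @param missing_rate Fraction of calls set missing at random (default 0).
#' @param seed Integer seed; all randomness flows through it.
#' @return A `genotype_matrix`: list with `calls` (lines x markers character
#'   matrix, values `"B73"`/`"Mo17"`/`NA`), `map` (tibble `marker_id`,
#'   `chrom`, `pos_cm`), and `line_ids`.
#' @examples
#' g <- simulate_genotypes(10, seed = 1)
#' dim(g$calls)
#' @export
simulate_genotypes <- function(n_lines, chromosomes = NULL,
                               expansion_factor = 4, missing_rate = 0,
                               seed = NULL) {
  if (!is.numeric(n_lines) || n_lines < 2) {
    abort("`n_lines` must be >= 2.", class = "surfqtl_invalid_argument")
  }
  if (is.null(chromosomes)) {
    chromosomes <- tibble::tibble(n_markers = rep(20L, 10), length_cm = 120)
  }
  if (any(chromosomes$n_markers < 2)) {
    abort("each chromosome needs >= 2 markers.", class = "surfqtl_invalid_argument")
  }
  check_scalar(expansion_factor, "expansion_factor")
  if (expansion_factor <= 0) {
    abort("`expansion_factor` must be positive.", class = "surfqtl_invalid_argument")
  }
  n_lines <- as.integer(n_lines)
  with_seed(seed, {
    maps <- purrr::imap(seq_len(nrow(chromosomes)), function(ci, i) {
      nm <- chromosomes$n_markers[ci]
      pos <- seq(0, chromosomes$length_cm[ci], length.out = nm)
      tibble::tibble(
        marker_id = sprintf("c%d_m%02d", ci, seq_len(nm)),
        chrom = ci, pos_cm = pos
      )
    })
    map <- dplyr::bind_rows(maps)
    alleles <- c("B73", "Mo17")
    calls <- matrix(NA_character_, n_lines, nrow(map))
    col0 <- 0L
    for (ci in seq_len(nrow(chromosomes))) {
      nm <- chromosomes$n_markers[ci]
      pos <- maps[[ci]]$pos_cm
      # Haldane map function on the expanded distances
      d <- diff(pos) * expansion_factor
      r <- 0.5 * (1 - exp(-2 * d / 100))
      state <- matrix(0L, n_lines, nm)
      state[, 1] <- stats::rbinom(n_lines, 1L, 0.5)
      for (j in seq_len(nm - 1L)) {
        switch <- stats::rbinom(n_lines, 1L, r[j])
        state[, j + 1L] <- (state[, j] + switch) %% 2L
      }
      calls[, col0 + seq_len(nm)] <- alleles[state + 1L]
      col0 <- col0 + nm
    }
    if (missing_rate > 0) {
      drop <- matrix(runif(length(calls)) < missing_rate, n_lines)
      # keep at least one non-missing call per line
      for (i in seq_len(n_lines)) if (all(drop[i, ])) drop[i, 1] <- FALSE
      calls[drop] <- NA_character_
    }
    line_ids <- sprintf("RIL%03d", seq_len(n_lines))
    dimnames(calls) <- list(line_ids, map$marker_id)
    new_genotype_matrix(calls, map)
  })
}

new_genotype_matrix <- function(calls, map) {
  structure(
    list(calls = calls, map = tibble::as_tibble(map),
         line_ids = rownames(calls)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers on %d chromosome(s); %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::as_tibble(x$calls, rownames = "line_id") |>
    tidyr::pivot_longer(-"line_id", names_to = "marker_id", values_to = "call") |>
    dplyr::left_join(x$map, by = "marker_id")
}

#' Face-centered two-stress design
#'
#' Builds the nine-combination face-centered response-surface design over
#' five drought and five nitrogen levels: the four extreme corners and four
#' face points at the corner replicate count, and the centre point at the
#' (larger) centre count, concentrating replication where quadratic fits
#' need it most.
#'
#' @param water_levels,nitrogen_levels Ascending stress levels (percent);
#'   defaults are the study's levels.
#' @param reps Named counts `c(corner = 4, center = 8)` (per line).
#' @param combos Optional explicit tibble (`water_pct`, `nitrogen_pct`,
#'   `n_rep`) overriding the default nine combinations; levels must be
#'   members of the level sets.
#' @return A `stress_design` tibble: `water_pct`, `nitrogen_pct`, `n_rep`,
#'   `role`.
#' @examples
#' build_design()
#' @export
build_design <- function(water_levels = c(8, 20, 50, 80, 92),
                         nitrogen_levels = c(0, 2.5, 7.5, 12.5, 15),
                         reps = c(corner = 4, center = 8),
                         combos = NULL) {
  check_finite(water_levels, "water_levels")
  check_finite(nitrogen_levels, "nitrogen_levels")
  if (is.unsorted(water_levels, strictly = TRUE) ||
      is.unsorted(nitrogen_levels, strictly = TRUE)) {
    abort("stress levels must be sorted strictly ascending.",
          class = "surfqtl_invalid_argument")
  }
  if (!is.null(combos)) {
    bad <- !(combos$water_pct %in% water_levels) |
      !(combos$nitrogen_pct %in% nitrogen_levels)
    if (any(bad)) {
      abort("`combos` reference stress values outside the level sets.",
            class = "surfqtl_invalid_argument")
    }
    design <- tibble::as_tibble(combos)
    if (is.null(design[["role"]])) design$role <- "custom"
  } else {
    w <- water_levels; n <- nitrogen_levels
    mid <- function(x) x[ceiling(length(x) / 2)]
    second <- function(x) if (length(x) >= 2) x[2] else x[1]
    fourth <- function(x) if (length(x) >= 4) x[length(x) - 1] else x[length(x)]
    if (length(w) == 1 && length(n) == 1) {
      design <- tibble::tibble(water_pct = w, nitrogen_pct = n,
                               n_rep = unname(reps["center"]), role = "center")
    } else {
      corners <- tidyr::expand_grid(water_pct = range(w), nitrogen_pct = range(n))
      faces <- tibble::tibble(
        water_pct = c(second(w), fourth(w), mid(w), mid(w)),
        nitrogen_pct = c(mid(n), mid(n), second(n), fourth(n))
      )
      design <- dplyr::bind_rows(
        dplyr::mutate(corners, n_rep = unname(reps["corner"]), role = "corner"),
        dplyr::mutate(faces, n_rep = unname(reps["corner"]), role = "face"),
        tibble::tibble(water_pct = mid(w), nitrogen_pct = mid(n),
                       n_rep = unname(reps["center"]), role = "center")
      )
      design <- dplyr::distinct(design, .data$water_pct, .data$nitrogen_pct,
                                .keep_all = TRUE)
    }
  }
  if (any(design$n_rep <= 0)) {
    abort("replicate counts must be positive.", class = "surfqtl_invalid_argument")
  }
  structure(design, class = c("stress_design", class(design)),
            water_levels = water_levels, nitrogen_levels = nitrogen_levels)
}

#' Allele-sharing kinship matrix
#'
#' Identity-in-state relatedness: for each pair of lines, the proportion of
#' markers non-missing in both that carry the same allele; the diagonal is
#' 1. A small ridge keeps the matrix numerically positive definite and the
#' result is rescaled so the mean diagonal is 1. This simple estimator
#' provides the relative covariance scale the mixed-model scan needs.
#'
#' @param genotypes A `genotype_matrix`.
#' @param ridge Diagonal ridge (default 1e-6).
#' @return A `kinship_matrix`: symmetric lines x lines numeric matrix.
#' @export
compute_kinship <- function(genotypes, ridge = 1e-6) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  calls <- genotypes$calls
  if (nrow(calls) < 2) abort("need >= 2 lines.", class = "surfqtl_invalid_argument")
  x <- (calls == "B73") * 1          # NA propagates
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  shared <- obs %*% t(obs)           # markers non-missing in both
  if (any(shared == 0)) {
    abort("some line pair shares no non-missing markers.",
          class = "surfqtl_missing_data")
  }
  same <- x0 %*% t(x0) + (obs - x0) %*% t(obs - x0)
  k <- same / shared
  k <- (k + t(k)) / 2
  diag(k) <- 1
  # pairwise-complete estimation can leave negative eigenvalues when calls
  # are missing; clip them so the matrix is a valid covariance scale
  eig <- eigen(k, symmetric = TRUE)
  if (min(eig$values) < 0) {
    k <- eig$vectors %*% (pmax(eig$values, 0) * t(eig$vectors))
    k <- (k + t(k)) / 2
    dimnames(k) <- dimnames(shared)
  }
  k <- (k + ridge * diag(nrow(k))) / (mean(diag(k)) + ridge)
  structure(k, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d lines; off-diagonal range [%.3f, %.3f]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Simulate growth phenotypes under the two-stress design
#'
#' Generates one record per line, design combination, and replicate. The
#' growth variable (difference in height) decomposes exactly as the scan's
#' model assumes:
#' \deqn{\Delta z = \mathrm{baseline} + \sum_m f_{m,\mathrm{allele}}(x_w, x_n)
#'       + \alpha_{line} + \varepsilon,}
#' with causal allele effects given by producing functions, the vector of
#' line effects drawn once from N(0, `sigma_line`^2 K), and i.i.d. Gaussian
#' residuals. Initial height is N(`init_mean`, `init_sd`^2) and final height
#' is initial plus the difference.
#'
#' @param genotypes A `genotype_matrix`.
#' @param design A [build_design()] tibble.
#' @param causal Named list: marker_id -> list(B73 = producing_function,
#'   Mo17 = producing_function). NULL for no genetic effect. Lines missing
#'   a call at a causal marker receive the average of the two allele
#'   effects.
#' @param baseline Mean growth (cm) at the design centre, default 25.
#' @param sigma_line SD of the kinship-structured line effect (default 2).
#' @param sigma_resid Residual SD (default 3).
#' @param kinship Optional `kinship_matrix` (identity if NULL).
#' @param init_mean,init_sd Initial-height distribution (defaults 15, 2 cm).
#' @param seed Integer seed.
#' @return A `phenotype_table` tibble: `line_id`, `water_pct`,
#'   `nitrogen_pct`, `xw`, `xn`, `initial_height_cm`, `final_height_cm`,
#'   `diff_height_cm`.
#' @export
simulate_phenotypes <- function(genotypes, design = build_design(),
                                causal = NULL, baseline = 25,
                                sigma_line = 2, sigma_resid = 3,
                                kinship = NULL, init_mean = 15, init_sd = 2,
                                seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  for (nm in c("baseline", "sigma_line", "sigma_resid", "init_mean", "init_sd")) {
    check_scalar(get(nm), nm)
  }
  if (sigma_line < 0 || sigma_resid < 0 || init_sd < 0) {
    abort("variances must be >= 0.", class = "surfqtl_invalid_argument")
  }
  if (!is.null(causal)) {
    missing_mk <- setdiff(names(causal), colnames(genotypes$calls))
    if (length(missing_mk)) {
      abort(paste("causal markers absent from genotypes:",
                  paste(missing_mk, collapse = ", ")),
            class = "surfqtl_invalid_argument")
    }
  }
  lines <- genotypes$line_ids
  q <- length(lines)
  with_seed(seed, {
    # line effects: alpha ~ N(0, sigma_line^2 K)
    if (sigma_line > 0) {
      kmat <- if (is.null(kinship)) diag(q) else unclass(kinship)
      if (!is.null(kinship) &&
          (nrow(kmat) != q || !all(rownames(kinship) %in% lines) &&
             !is.null(rownames(kinship)))) {
        kmat <- kmat[lines, lines]
      }
      ch <- tryCatch(chol(kmat), error = function(e) {
        abort("kinship matrix is not positive semi-definite.",
              class = "surfqtl_model_specification")
      })
      alpha <- as.numeric(t(ch) %*% rnorm(q)) * sigma_line
    } else {
      alpha <- rep(0, q)
    }
    names(alpha) <- lines

    slots <- tidyr::uncount(
      tibble::as_tibble(design)[c("water_pct", "nitrogen_pct", "n_rep")],
      .data$n_rep
    )
    recs <- tidyr::expand_grid(line_id = lines, slots)
    recs$xw <- recs$water_pct - 50
    recs$xn <- recs$nitrogen_pct - 7.5

    genetic <- rep(0, nrow(recs))
    if (!is.null(causal)) {
      for (mk in names(causal)) {
        pars <- causal[[mk]]
        call_at <- genotypes$calls[recs$line_id, mk]
        zB <- evaluate_producing(pars$B73, recs$xw, recs$xn)
        zM <- evaluate_producing(pars$Mo17, recs$xw, recs$xn)
        eff <- ifelse(is.na(call_at), (zB + zM) / 2,
                      ifelse(call_at == "B73", zB, zM))
        genetic <- genetic + eff
      }
    }
    n <- nrow(recs)
    diff <- baseline + genetic + unname(alpha[recs$line_id]) +
      rnorm(n, 0, sigma_resid)
    init <- rnorm(n, init_mean, init_sd)
    out <- tibble::tibble(
      line_id = recs$line_id,
      water_pct = recs$water_pct, nitrogen_pct = recs$nitrogen_pct,
      xw = recs$xw, xn = recs$xn,
      initial_height_cm = init,
      final_height_cm = init + diff,
      diff_height_cm = diff
    )
    structure(out, class = c("phenotype_table", class(out)))
  })
}
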