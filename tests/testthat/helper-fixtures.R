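# Fixtures built in code: tiny genotype sets, hand-made scans and meshes.

# genotype matrix from an explicit call matrix (lines x markers)
make_genotypes <- function(calls, chrom = NULL, pos = NULL) {
  nm <- ncol(calls)
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("m%02d", seq_len(nm))
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("L%02d", seq_len(nrow(calls)))
  map <- tibble::tibble(
    marker_id = colnames(calls),
    chrom = chrom %||% rep(1L, nm),
    pos_cm = pos %||% seq(0, by = 10, length.out = nm)
  )
  structure(list(calls = calls, map = map, line_ids = rownames(calls)),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scan_result skeleton for exercising smoothing/adjustment/calling alone
make_scan <- function(raw_p, chrom = rep(1L, length(raw_p)), smoothed_p = NULL) {
  n <- length(raw_p)
  tb <- tibble::tibble(
    marker_id = sprintf("m%02d", seq_len(n)),
    chrom = chrom,
    pos_cm = stats::ave(rep(0, n), chrom, FUN = function(x) seq(0, by = 10, length.out = length(x))),
    order = stats::ave(seq_len(n), chrom, FUN = seq_along),
    n_obs = rep(100L, n),
    F = rep(1, n),
    raw_p = raw_p,
    skipped = is.na(raw_p)
  )
  if (!is.null(smoothed_p)) tb$smoothed_p <- smoothed_p
  structure(tb, class = c("scan_result", class(tb)),
            vc = c(sigma2_line = 1, sigma2_resid = 1))
}

# small realistic simulated data set shared by scan tests
sim_small <- function(seed, n_lines = 60, causal = NULL, sigma_line = 1,
                      sigma_resid = 2, n_markers = 6, kin = TRUE) {
  g <- simulate_genotypes(n_lines,
                          tibble::tibble(n_markers = n_markers, length_cm = 100),
                          seed = seed)
  k <- if (kin) compute_kinship(g) else NULL
  ph <- simulate_phenotypes(g, build_design(), causal = causal, baseline = 25,
                            sigma_line = sigma_line, sigma_resid = sigma_resid,
                            kinship = k, seed = seed + 1)
  list(genotypes = g, kinship = k, phenotypes = ph)
}
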