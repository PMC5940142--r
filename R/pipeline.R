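#' Run the full simulate-scan-fit-compare pipeline
#'
#' Drives the whole analysis from one configuration: simulates genotypes,
#' design, kinship and phenotypes; runs the kinship mixed-model F-scan with
#' Simes smoothing and Sidak/FDR calling; grid-maximises and classifies the
#' reference surfaces; fits producing-function parameters over their
#' meshes; scores all experimental-vs-model surface pairs; and writes every
#' table (plus heatmap/projection PNGs when `write_plots` is on and a
#' graphics device is available) under `out_dir` together with a run log.
#' Outputs are deterministic given the configured seed.
#'
#' @param config A `pipeline_config` (see [default_config()] and
#'   [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  config <- validate_config(config)
  if (missing(out_dir)) abort("`out_dir` is required.",
                              class = "surfqtl_invalid_argument")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  unlink(log_path)
  logf("config", sprintf("seed=%d n_lines=%d causal=%s",
                         config$seed, config$n_lines,
                         config$causal_marker %||% "none"))
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      logf(stage, paste("ERROR:", conditionMessage(e)))
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)),
            class = "surfqtl_pipeline_error")
    })
  }

  geno <- run_stage("simulate", {
    ch <- config$chromosomes
    g <- simulate_genotypes(
      config$n_lines,
      tibble::tibble(n_markers = rep(ch$markers_per_chrom, ch$n),
                     length_cm = ch$length_cm),
      expansion_factor = config$expansion_factor,
      missing_rate = config$missing_rate,
      seed = config$seed
    )
    write_genotypes(g, file.path(out_dir, "genotypes.csv"),
                    file.path(out_dir, "marker_map.csv"))
    g
  })
  design <- build_design(config$design$water_levels,
                         config$design$nitrogen_levels,
                         reps = unlist(config$design$reps))
  kin <- run_stage("kinship", compute_kinship(geno))
  ph <- run_stage("phenotypes", {
    causal <- if (!is.null(config$causal_marker)) {
      stats::setNames(
        list(list(B73 = example_producing_params("B73-like"),
                  Mo17 = example_producing_params("Mo17-like"))),
        config$causal_marker
      )
    }
    p <- simulate_phenotypes(
      geno, design, causal = causal,
      baseline = config$phenotype$baseline,
      sigma_line = config$phenotype$sigma_line,
      sigma_resid = config$phenotype$sigma_resid,
      kinship = kin,
      init_mean = config$phenotype$init_mean,
      init_sd = config$phenotype$init_sd,
      seed = config$seed + 1L
    )
    write_phenotypes(p, file.path(out_dir, "phenotypes.csv"))
    p
  })
  logf("phenotypes", sprintf("%d records", nrow(ph)))

  scan <- run_stage("scan", {
    s <- marker_scan(ph, geno, kin, min_class = config$scan$min_class)
    s <- simes_smooth(s, window = config$scan$simes_window)
    s <- adjust_scan(s, alpha = config$scan$alpha)
    readr::write_tsv(
      tibble::as_tibble(s)[c("marker_id", "chrom", "order", "F", "raw_p",
                             "smoothed_p", "fdr_p", "sidak_sig")],
      file.path(out_dir, "scan.tsv")
    )
    s
  })
  qtl <- run_stage("qtl", {
    q <- call_qtl(scan, "sidak", alpha = config$scan$alpha)
    readr::write_tsv(q, file.path(out_dir, "qtl_sidak.tsv"))
    readr::write_tsv(call_qtl(scan, "fdr", alpha = config$scan$alpha),
                     file.path(out_dir, "qtl_fdr.tsv"))
    q
  })
  logf("scan", sprintf("%d markers, %d Sidak interval(s)",
                       nrow(scan), nrow(qtl)))

  grid <- eval_grid(unlist(config$grid$water), unlist(config$grid$nitrogen),
                    config$grid$step)
  peaks <- run_stage("peaks", {
    pk <- surface_peaks(allele_surface_coefs(), grid)
    write_surface_coefs(allele_surface_coefs(),
                        file.path(out_dir, "surface_coefs.csv"))
    readr::write_csv(
      dplyr::mutate(pk, xw = round(.data$xw, 1), xn = round(.data$xn, 1),
                    zmax = round(.data$zmax, 1)),
      file.path(out_dir, "surface_peaks.csv")
    )
    pk
  })

  fits <- run_stage("producing_fit", {
    surfaces <- allele_surfaces()
    f <- purrr::map_dfr(surfaces, function(s) {
      mesh <- withCallingHandlers(
        absolute_mesh(s, grid = grid,
                      fractions = unlist(config$mesh$contour_fractions)),
        surfqtl_zero_length_ray = function(w) invokeRestart("muffleWarning")
      )
      fit <- fit_producing(mesh, c = if (curvature_sign(s) > 0) 1 else -1)
      write_mesh(mesh, file.path(out_dir, sprintf("mesh_%s.tsv", s$label)))
      p <- fit$params
      sp <- sign_pattern(p)
      tibble::tibble(label = s$label, a = p$a, b = p$b, c = p$c, d = p$d,
                     e = p$e, s = fit$s, sgn_a = sp[["a"]], sgn_b = sp[["b"]],
                     sgn_d = sp[["d"]], sgn_e = sp[["e"]])
    })
    readr::write_csv(f, file.path(out_dir, "producing_fits.csv"))
    f
  })

  scores <- run_stage("compare", {
    sims <- as_producing_list(
      dplyr::mutate(fits, label = .data$label)[c("label", "a", "b", "c", "d", "e")]
    )
    sc <- compare_all(allele_surfaces(), sims, grid = grid,
                      slopes = unlist(config$mesh$slopes),
                      points_per_ray = config$mesh$points_per_ray)
    for (which in c("rho", "theta", "delta_zr")) {
      m <- tibble::as_tibble(sc[[which]], rownames = "pair")
      readr::write_tsv(m, file.path(out_dir, sprintf("scores_%s.tsv", which)))
    }
    readr::write_tsv(sc$excluded, file.path(out_dir, "excluded_surfaces.tsv"))
    sc
  })
  logf("compare", sprintf("%d pairs scored, %d surface(s) excluded",
                          nrow(scores$pairs), nrow(scores$excluded)))

  if (isTRUE(config$write_plots) && capabilities("png")) {
    run_stage("plots", {
      for (which in c("rho", "theta", "delta_zr")) {
        ggplot2::ggsave(file.path(out_dir, sprintf("heatmap_%s.png", which)),
                        autoplot(scores, score = which),
                        width = 9, height = 5, dpi = 150)
      }
      ggplot2::ggsave(file.path(out_dir, "projections.png"),
                      plot_surface_projections(allele_surfaces(), grid),
                      width = 10, height = 5, dpi = 150)
    })
    logf("plots", "heatmaps and projections written")
  }
  logf("done", "pipeline complete")
  invisible(list(genotypes = geno, design = design, kinship = kin,
                 phenotypes = ph, scan = scan, qtl = qtl, peaks = peaks,
                 producing_fits = fits, scores = scores, out_dir = out_dir))
}
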