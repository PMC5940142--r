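# File formats: plain CSV/TSV with documented headers (the domain has no
# binary standard). All writers produce files the package's own readers
# round-trip exactly.

fmt_error <- function(...) {
  abort(sprintf(...), class = "surfqtl_format_error")
}

check_header <- function(found, wanted, path) {
  if (!all(wanted %in% found)) {
    fmt_error("malformed header in '%s': expected columns %s", path,
              paste(wanted, collapse = ", "))
  }
}

#' Read and write phenotype tables
#'
#' CSV layout: `line_id,water_pct,nitrogen_pct,initial_height_cm,
#' final_height_cm,diff_height_cm`. On read, stress percentages are
#' recentred (water minus 50, nitrogen minus 7.5) into `xw`, `xn` with the
#' originals preserved, and `diff_height_cm` must equal
#' `final - initial` to within 1e-6 (violations are reported by row).
#'
#' @param path CSV path.
#' @param x A `phenotype_table`.
#' @return `read_phenotypes()` returns a `phenotype_table` tibble;
#'   `write_phenotypes()` returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  wanted <- c("line_id", "water_pct", "nitrogen_pct", "initial_height_cm",
              "final_height_cm", "diff_height_cm")
  check_header(names(tb), wanted, path)
  for (col in wanted[-1]) {
    if (!is.numeric(tb[[col]])) {
      fmt_error("non-numeric values in column '%s' of '%s'", col, path)
    }
  }
  bad <- which(abs(tb$diff_height_cm -
                     (tb$final_height_cm - tb$initial_height_cm)) > 1e-6)
  if (length(bad)) {
    fmt_error("'%s': diff_height_cm != final - initial at row %d", path, bad[1])
  }
  tb$xw <- tb$water_pct - 50
  tb$xn <- tb$nitrogen_pct - 7.5
  tb <- tb[c("line_id", "water_pct", "nitrogen_pct", "xw", "xn",
             "initial_height_cm", "final_height_cm", "diff_height_cm")]
  structure(tb, class = c("phenotype_table", class(tb)))
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(x, path) {
  cols <- c("line_id", "water_pct", "nitrogen_pct", "initial_height_cm",
            "final_height_cm", "diff_height_cm")
  readr::write_csv(tibble::as_tibble(x)[cols], path)
  invisible(path)
}

#' Read and write genotype matrices
#'
#' Genotype CSV: first column `line_id`, remaining columns one per marker
#' with calls coded `A` (B73 allele), `B` (Mo17 allele), `-` (missing).
#' Companion map CSV: `marker_id,chromosome,position_cM`. Every genotype
#' column must appear in the map.
#'
#' @param path Genotype CSV path.
#' @param map_path Marker map CSV path.
#' @param x A `genotype_matrix`.
#' @return `read_genotypes()` returns a `genotype_matrix`;
#'   `write_genotypes()` returns `path` invisibly.
#' @export
read_genotypes <- function(path, map_path) {
  tb <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (names(tb)[1] != "line_id") {
    fmt_error("malformed header in '%s': first column must be line_id", path)
  }
  mp <- readr::read_csv(map_path, show_col_types = FALSE)
  check_header(names(mp), c("marker_id", "chromosome", "position_cM"), map_path)
  markers <- names(tb)[-1]
  unmapped <- setdiff(markers, mp$marker_id)
  if (length(unmapped)) {
    fmt_error("'%s': marker '%s' missing from the map file", path, unmapped[1])
  }
  codes <- as.matrix(tb[-1])
  bad <- which(!codes %in% c("A", "B", "-"))
  if (length(bad)) {
    fmt_error("'%s': invalid genotype code '%s'", path, codes[bad[1]])
  }
  calls <- matrix(NA_character_, nrow(codes), ncol(codes),
                  dimnames = list(tb$line_id, markers))
  calls[codes == "A"] <- "B73"
  calls[codes == "B"] <- "Mo17"
  if (any(rowSums(!is.na(calls)) == 0)) {
    fmt_error("'%s': some line has no non-missing calls", path)
  }
  map <- tibble::tibble(marker_id = mp$marker_id, chrom = mp$chromosome,
                        pos_cm = mp$position_cM)
  map <- map[match(markers, map$marker_id), ]
  ord <- order(map$chrom, map$pos_cm)
  new_genotype_matrix(calls[, ord, drop = FALSE], map[ord, ])
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(x, path, map_path) {
  codes <- x$calls
  out <- matrix("-", nrow(codes), ncol(codes), dimnames = dimnames(codes))
  out[codes == "B73"] <- "A"
  out[codes == "Mo17"] <- "B"
  tb <- tibble::as_tibble(out, rownames = "line_id")
  readr::write_csv(tb, path)
  readr::write_csv(
    tibble::tibble(marker_id = x$map$marker_id, chromosome = x$map$chrom,
                   position_cM = x$map$pos_cm),
    map_path
  )
  invisible(path)
}

#' Read and write surface coefficient tables
#'
#' CSV layout (published column order):
#' `label,beta3,beta4,beta5,beta1,beta2,ell`.
#'
#' @param path CSV path.
#' @param x Data frame of coefficients.
#' @return A tibble of coefficients / `path` invisibly.
#' @export
read_surface_coefs <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  check_header(names(tb),
               c("label", "beta3", "beta4", "beta5", "beta1", "beta2", "ell"),
               path)
  tb
}

#' @rdname read_surface_coefs
#' @export
write_surface_coefs <- function(x, path) {
  cols <- c("label", "beta3", "beta4", "beta5", "beta1", "beta2", "ell")
  readr::write_csv(tibble::as_tibble(x)[cols], path)
  invisible(path)
}

#' Read and write producing-function parameter tables
#'
#' CSV layout: `label,a,b,c,d,e,s` (`s` may be NA for parameter sets that
#' were not fitted).
#'
#' @param path CSV path.
#' @param x Data frame of parameters.
#' @return A tibble of parameters / `path` invisibly.
#' @export
read_producing_params <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  check_header(names(tb), c("label", "a", "b", "c", "d", "e", "s"), path)
  tb
}

#' @rdname read_producing_params
#' @export
write_producing_params <- function(x, path) {
  x <- tibble::as_tibble(x)
  if (is.null(x[["s"]])) x$s <- NA_real_
  readr::write_csv(x[c("label", "a", "b", "c", "d", "e", "s")], path)
  invisible(path)
}

#' Write a mesh as TSV
#'
#' Columns `surface,flavor,ray,index,xw,xn,z`, preceded by `#`-prefixed
#' header lines recording the mesh specification.
#'
#' @param mesh A `mesh_points` tibble.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  hdr <- c(
    sprintf("# flavor: %s", attr(mesh, "flavor") %||% "custom"),
    sprintf("# surface: %s", attr(mesh, "surface_label") %||% "surface"),
    sprintf("# peak: xw=%g xn=%g", attr(mesh, "peak")$xw, attr(mesh, "peak")$xn)
  )
  writeLines(hdr, path)
  tb <- tibble::as_tibble(mesh)
  tb <- tibble::tibble(surface = attr(mesh, "surface_label") %||% "surface",
                       flavor = attr(mesh, "flavor") %||% "custom",
                       tb[c("ray", "index", "xw", "xn", "z")])
  readr::write_tsv(tb, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' A fully-populated configuration reproducing the default pipeline with no
#' other input: the study's stress levels and evaluation grid, 89 lines,
#' one causal marker with the illustrative dome/trough allele surfaces, and
#' the default scan and mesh settings.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    n_lines = 89L,
    chromosomes = list(n = 10L, markers_per_chrom = 20L, length_cm = 120),
    expansion_factor = 4,
    missing_rate = 0,
    design = list(
      water_levels = c(8, 20, 50, 80, 92),
      nitrogen_levels = c(0, 2.5, 7.5, 12.5, 15),
      reps = c(corner = 4, center = 8)
    ),
    phenotype = list(baseline = 25, sigma_line = 2, sigma_resid = 3,
                     init_mean = 15, init_sd = 2),
    causal_marker = "c1_m10",
    grid = list(water = c(-42, 42), nitrogen = c(-7.5, 7.5), step = 0.5),
    scan = list(simes_window = 5L, alpha = 0.05, min_class = 10L),
    mesh = list(slopes = default_ray_slopes(), points_per_ray = 10L,
                contour_fractions = c(0.05, 0.15, 0.30, 0.50)),
    write_plots = FALSE
  ), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML with the keys of [default_config()]; unspecified keys take the
#' defaults, numeric options are validated against their documented ranges.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        merge_into(base[[nm]], upd[[nm]])
      } else {
        upd[[nm]]
      }
    }
    base
  }
  cfg <- merge_into(unclass(cfg), user)
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$n_lines < 2) fmt_error("config: n_lines must be >= 2")
  if (cfg$scan$alpha <= 0 || cfg$scan$alpha >= 1) {
    fmt_error("config: scan alpha must be in (0, 1)")
  }
  if (cfg$scan$simes_window %% 2 != 1) {
    fmt_error("config: simes_window must be odd")
  }
  if (cfg$grid$step <= 0) fmt_error("config: grid step must be positive")
  if (cfg$phenotype$sigma_line < 0 || cfg$phenotype$sigma_resid < 0) {
    fmt_error("config: variance components must be >= 0")
  }
  if (cfg$mesh$points_per_ray < 2) {
    fmt_error("config: points_per_ray must be >= 2")
  }
  cfg
}
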