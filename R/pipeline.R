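## Pipeline entry points tying surface I/O, the OPCR engine and the
## statistical stage into reproducible one-call analyses.

#' Compute OPCR for a surface file
#'
#' Reads a surface (PLY mesh, XYZ point cloud, or Surfer ASCII grid, chosen
#' by file extension), rasterizes point data into an occlusal height map,
#' standardizes the tooth row to `rows_per_tooth` data rows per tooth, and
#' computes OPC over the rotation ladder. Optionally writes the result as
#' JSON plus a per-rotation CSV.
#'
#' @param surface_path path to `.ply`, `.xyz` (or `.txt`), or `.grd` file.
#' @param n_teeth teeth in the scanned row.
#' @param rows_per_tooth standardized data rows per tooth.
#' @param params an [opc_params()].
#' @param row_axis mesiodistal axis of the input coordinates (see
#'   [grid_point_cloud()]).
#' @param out_dir if given, writes `<stem>_opcr.json` and `<stem>_opcr.csv`
#'   there.
#' @return An `opcr_result` (invisibly when `out_dir` is given).
#' @export
run_opcr <- function(surface_path, n_teeth, rows_per_tooth = 50L,
                     params = opc_params(), row_axis = "y", out_dir = NULL) {
  if (!file.exists(surface_path))
    stop(sprintf("file not found: %s", surface_path), call. = FALSE)
  ext <- tolower(tools::file_ext(surface_path))
  hm <- switch(ext,
    ply = {
      mesh <- read_ply(surface_path)
      grid_point_cloud(mesh$vertices, target_rows = n_teeth * rows_per_tooth,
                       row_axis = row_axis)
    },
    xyz = , txt = {
      cloud <- read_xyz(surface_path)
      grid_point_cloud(cloud, target_rows = n_teeth * rows_per_tooth,
                       row_axis = row_axis)
    },
    grd = read_surfer_grid(surface_path),
    stop(sprintf("unrecognized surface format '.%s' (expected .ply, .xyz or .grd)",
                 ext), call. = FALSE))
  trg <- standardize_tooth_row(hm, n_teeth = n_teeth,
                               rows_per_tooth = rows_per_tooth)
  res <- compute_opcr(trg, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- tools::file_path_sans_ext(basename(surface_path))
    jsonlite::write_json(
      list(source = surface_path, n_teeth = n_teeth,
           rows_per_tooth = rows_per_tooth,
           opcr = res$opcr, opc_per_rotation = res$opc_per_rotation,
           n_rotations = res$n_rotations, step_deg = res$step_deg,
           params = unclass(params)),
      file.path(out_dir, paste0(stem, "_opcr.json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(
      data.frame(rotation = seq_len(res$n_rotations) - 1L,
                 offset_deg = (seq_len(res$n_rotations) - 1L) * res$step_deg,
                 opc = res$opc_per_rotation),
      file.path(out_dir, paste0(stem, "_opcr.csv")), row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Full statistical analysis of a specimen table
#'
#' Runs the whole specimen-level analysis: derived measures, per-order
#' summaries, Mann-Whitney comparisons of the orders (Carnivora reported
#' first), size correlations, the OLS association between upper and lower
#' log OPCR, and the two five-model AICc selection tables with confidence
#' sets and model-averaged coefficients.
#'
#' @param table a `specimen_table`, a CSV path, or `"table1"` (default) for
#'   the packaged 34-specimen table.
#' @param correlation_space,metric,conf_level,n_grid passed to
#'   [build_selection_table()].
#' @return An `analysis_report` list: `specimens`, `group_summary`, `tests`,
#'   `correlations`, `ols_upper_lower`, `selection_upper`, `selection_lower`,
#'   `averaged_upper`, `averaged_lower`, `config`.
#' @examples
#' \donttest{
#' rep <- analyze_specimens("table1")
#' rep$selection_upper
#' }
#' @export
analyze_specimens <- function(table = "table1",
                              correlation_space = "candidate_covariates",
                              metric = NULL, conf_level = 0.95,
                              n_grid = 150L) {
  df <- if (is.character(table)) load_specimen_table(table) else table
  df <- derive_measures(df)
  carn <- df$order_name == "Carnivora"
  if (!any(carn) || all(carn))
    stop("specimen table must hold both orders for the group comparisons",
         call. = FALSE)
  utest <- function(var) {
    r <- mann_whitney_u(df[[var]][carn], df[[var]][!carn])
    data.frame(measure = var, U = r$U, p = r$p, method = r$method)
  }
  tests <- do.call(rbind, lapply(
    c("avg_upper", "avg_lower", "rt", "rd", "a"), utest))
  correlations <- list(
    t_w = pearson_r(log(df$t), df$w),     # log motion distance vs raw width
    d_w = pearson_r(log(df$d), df$w),
    t_w_raw = pearson_r(df$t, df$w),
    d_w_raw = pearson_r(df$d, df$w))
  ols <- ols_fit(df$ln_upper, as.matrix(df[, "ln_lower", drop = FALSE]))
  sel_u <- build_selection_table(df, "upper",
                                 correlation_space = correlation_space,
                                 metric = metric, conf_level = conf_level,
                                 n_grid = n_grid)
  sel_l <- build_selection_table(df, "lower",
                                 correlation_space = correlation_space,
                                 metric = metric, conf_level = conf_level,
                                 n_grid = n_grid)
  num_cols <- c("upper_opcr", "lower_opcr", "avg_upper", "avg_lower",
                "t", "d", "a", "w")
  gs <- do.call(rbind, lapply(split(df[num_cols], df$order_name), colMeans))
  structure(list(
    specimens = df,
    group_summary = data.frame(order_name = rownames(gs),
                               n = as.vector(table(df$order_name)[rownames(gs)]),
                               gs, row.names = NULL),
    tests = tests,
    correlations = correlations,
    ols_upper_lower = ols,
    selection_upper = sel_u,
    selection_lower = sel_l,
    averaged_upper = model_average(sel_u),
    averaged_lower = model_average(sel_l),
    config = list(correlation_space = correlation_space,
                  metric = attr(sel_u, "metric"), conf_level = conf_level,
                  n_grid = n_grid,
                  package_version = as.character(utils::packageVersion("opcrkin")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Specimen analysis ==\n")
  print(x$group_summary, digits = 4)
  cat("\nOrder comparisons (Mann-Whitney, Carnivora first):\n")
  print(transform(x$tests, p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("\nln upper ~ ln lower OPCR: r^2 = %.3f, logLik = %.2f, AICc = %.2f\n",
              x$ols_upper_lower$r_squared, x$ols_upper_lower$loglik,
              x$ols_upper_lower$aicc))
  cat(sprintf("cor(ln t, w) = %.2f, cor(ln d, w) = %.2f\n\n",
              x$correlations$t_w, x$correlations$d_w))
  print(x$selection_upper)
  cat("\n")
  print(x$selection_lower)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serializes the report as JSON (full floating-point precision) plus the two
#' selection tables as CSV.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sel_as_list <- function(s) {
    list(table = as.data.frame(s), response = attr(s, "response"),
         metric = attr(s, "metric"),
         correlation_space = attr(s, "correlation_space"))
  }
  payload <- list(
    schema = "opcrkin-analysis-report/1",
    group_summary = report$group_summary,
    tests = report$tests,
    correlations = report$correlations,
    ols_upper_lower = report$ols_upper_lower[
      c("coefficients", "sigma", "loglik", "K", "n", "aicc", "r_squared")],
    selection_upper = sel_as_list(report$selection_upper),
    selection_lower = sel_as_list(report$selection_lower),
    averaged_upper = as.list(report$averaged_upper),
    averaged_lower = as.list(report$averaged_lower),
    config = report$config)
  jsonlite::write_json(payload, file.path(dir, "analysis_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(as.data.frame(report$selection_upper),
                   file.path(dir, "selection_upper.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$selection_lower),
                   file.path(dir, "selection_lower.csv"), row.names = FALSE)
  invisible(dir)
}

#' Generate synthetic data files
#'
#' Writes a synthetic surface (Surfer grid + XYZ) or a simulated specimen
#' table (CSV) plus a JSON metadata sidecar recording the spec and seed.
#' Outputs are byte-identical across runs of the same spec.
#'
#' @param spec a [surface_spec()] or [simulation_params()].
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
simulate_to_dir <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(spec, "surface_spec")) {
    hm <- make_surface(spec)
    grd <- file.path(out_dir, sprintf("surface_%s.grd", spec$kind))
    xyz <- file.path(out_dir, sprintf("surface_%s.xyz", spec$kind))
    write_surfer_grid(hm, grd)
    yy <- hm$origin[1] + (seq_len(nrow(hm$values)) - 1) * hm$spacing_row
    xx <- hm$origin[2] + (seq_len(ncol(hm$values)) - 1) * hm$spacing_col
    pts <- cbind(rep(xx, each = nrow(hm$values)),
                 rep(yy, times = ncol(hm$values)),
                 as.vector(hm$values))[as.vector(hm$mask), , drop = FALSE]
    write_xyz(pts, xyz)
    meta <- file.path(out_dir, sprintf("surface_%s.json", spec$kind))
    jsonlite::write_json(unclass(spec), meta, auto_unbox = TRUE, digits = NA)
    files <- c(grd, xyz, meta)
  } else if (inherits(spec, "simulation_params")) {
    df <- simulate_specimens(spec)
    csv <- file.path(out_dir, "specimens.csv")
    utils::write.csv(format(as.data.frame(df), digits = 15, trim = TRUE),
                     csv, row.names = FALSE, quote = FALSE)
    meta <- file.path(out_dir, "specimens.json")
    jsonlite::write_json(unclass(spec)[setdiff(names(unclass(spec)), "cor_mat")],
                         meta, auto_unbox = TRUE, digits = NA)
    files <- c(csv, meta)
  } else {
    stop("`spec` must be a surface_spec or simulation_params", call. = FALSE)
  }
  invisible(files)
}
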