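#' CSV schemas
#'
#' The package reads and writes plain UTF-8 CSV with a header row and
#' "." as the decimal separator. Three schemas are defined:
#' \describe{
#'   \item{growth}{`s1_mg_l` (nitrate-N, > 0), optional `s2_mg_l`
#'     (carbon, > 0), `mu_per_h` (>= 0).}
#'   \item{batch}{`time_h` (strictly increasing), `no3_mg_l`,
#'     `no2_mg_l` (>= 0), optional `toc_mg_l` and `biomass`, and `cc0`
#'     (constant column, the initial cell concentration).}
#'   \item{ct}{`condition`, `gene`, `role` (target/reference),
#'     `replicate`, `ct` (> 0).}
#' }
#' All concentrations are nitrogen mass for NO3-N / NO2-N, mg l^-1.
#'
#' @name csv-schemas
NULL

#' Read and validate a delimited table
#'
#' Reads a CSV file against one of the package schemas (see
#' \link{csv-schemas}) and either returns the typed table or raises an
#' error listing every row-level violation with its row number.
#'
#' @param path Path to a CSV file.
#' @param schema `"growth"`, `"batch"` or `"ct"`.
#' @return A [growth_table()], [batch_time_series()] or [ct_table()].
#' @export
validate_table <- function(path, schema = c("growth", "batch", "ct")) {
  schema <- match.arg(schema)
  if (!file.exists(path))
    stop(sprintf("input file does not exist: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- character()
  need <- function(cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s: missing required column(s): %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  row_check <- function(bad, msg) {
    if (any(bad, na.rm = TRUE))
      problems <<- c(problems, sprintf("row %d: %s", which(bad), msg))
  }
  out <- switch(schema,
    growth = {
      need(c("s1_mg_l", "mu_per_h"))
      row_check(!is.finite(df$s1_mg_l) | df$s1_mg_l <= 0,
                "s1_mg_l must be positive")
      row_check(!is.finite(df$mu_per_h) | df$mu_per_h < 0,
                "mu_per_h must be non-negative")
      if ("s2_mg_l" %in% names(df) && !all(is.na(df$s2_mg_l)))
        row_check(!is.finite(df$s2_mg_l) | df$s2_mg_l <= 0,
                  "s2_mg_l must be positive")
      if (length(problems) == 0L)
        growth_table(df$s1_mg_l, df$mu_per_h,
                     s2 = if ("s2_mg_l" %in% names(df) &&
                              !all(is.na(df$s2_mg_l))) df$s2_mg_l)
    },
    batch = {
      need(c("time_h", "no3_mg_l", "no2_mg_l", "cc0"))
      row_check(c(FALSE, diff(df$time_h) <= 0),
                "time_h must be strictly increasing")
      row_check(!is.finite(df$no3_mg_l) | df$no3_mg_l < 0,
                "no3_mg_l must be non-negative")
      row_check(!is.finite(df$no2_mg_l) | df$no2_mg_l < 0,
                "no2_mg_l must be non-negative")
      if (length(unique(df$cc0)) != 1L)
        problems <- c(problems, "cc0 must be constant across rows")
      if (length(problems) == 0L)
        batch_time_series(df$time_h, df$no3_mg_l, df$no2_mg_l,
                          biomass = if ("biomass" %in% names(df)) df$biomass,
                          cc0 = df$cc0[1],
                          toc = if ("toc_mg_l" %in% names(df)) df$toc_mg_l)
    },
    ct = {
      need(c("condition", "gene", "role", "replicate", "ct"))
      row_check(!df$role %in% c("target", "reference"),
                "role must be target or reference")
      row_check(!is.finite(df$ct) | df$ct <= 0, "ct must be positive")
      if (length(problems) == 0L)
        ct_table(df$condition, df$gene, df$role, df$replicate, df$ct)
    })
  if (length(problems))
    stop(sprintf("%s failed %s-schema validation:\n  %s", path, schema,
                 paste(problems, collapse = "\n  ")), call. = FALSE)
  out
}

#' @rdname read-write
#' @export
read_growth_table <- function(path) validate_table(path, "growth")

#' @rdname read-write
#' @export
read_batch_series <- function(path) validate_table(path, "batch")

#' @rdname read-write
#' @export
read_ct_table <- function(path) validate_table(path, "ct")

#' Read and write package tables as CSV
#'
#' Writers emit the canonical column layout of \link{csv-schemas};
#' readers validate on the way in. When the object carries generator
#' attributes (truth, seed) [write_dataset()] also writes a
#' `<path>.manifest.json` recording them.
#'
#' @param path CSV file path.
#' @param x Table to write.
#' @return Readers return the typed table; writers return `path`
#'   invisibly.
#' @name read-write
NULL

#' @rdname read-write
#' @export
write_growth_table <- function(x, path) {
  stopifnot(inherits(x, "growth_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read-write
#' @export
write_batch_series <- function(x, path) {
  stopifnot(inherits(x, "batch_ts"))
  df <- as.data.frame(x)
  df$cc0 <- attr(x, "cc0")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read-write
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a generated dataset together with its manifest
#'
#' @param x A table produced by one of the `gen_*` generators.
#' @param path Output CSV path; the manifest goes to
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  if (inherits(x, "growth_table")) write_growth_table(x, path)
  else if (inherits(x, "batch_ts")) write_batch_series(x, path)
  else if (inherits(x, "ct_table")) write_ct_table(x, path)
  else stop("unsupported table type", call. = FALSE)
  truth <- attr(x, "truth")
  manifest <- list(
    package = "denitkin",
    version = as.character(utils::packageVersion("denitkin")),
    seed = attr(x, "seed"),
    truth = if (!is.null(truth)) unclass(truth))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / re-read a model-comparison report
#'
#' The [fit_report()] tibble round-trips through CSV: every report the
#' package writes can be re-read by its own reader.
#'
#' @param fits A `fit_collection` or the [fit_report()] tibble itself.
#' @param path CSV path.
#' @return `read_fit_report` returns the report tibble.
#' @export
write_fit_report <- function(fits, path) {
  rep <- if (inherits(fits, "fit_collection")) fit_report(fits) else fits
  utils::write.csv(as.data.frame(rep), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fitting_number", "mu_max", "r_squared", "converged")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("not a fit report (missing %s)",
                 paste(miss, collapse = ", ")), call. = FALSE)
  tibble::as_tibble(df)
}

cli_usage <- function() {
  paste(
    "usage: denitkin <command> [options]",
    "",
    "commands:",
    "  fit-all    --input growth.csv --out DIR",
    "  fit-single --input growth.csv --substrate s1|s2 --kind KIND --out DIR",
    "  fit-double --input growth.csv --kind1 KIND --kind2 KIND --out DIR",
    "  arrhenius  --input arrhenius.csv --out DIR   (columns: temperature_K, mu_max)",
    "  metrics    --input batch.csv --out DIR",
    "  ddct       --input ct.csv --control LABEL --out DIR",
    "  simulate   growth|batch|ct|arrhenius --seed N --out DIR",
    sep = "\n")
}

cli_opts <- function(argv) {
  opts <- list(positional = character())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      if (i == length(argv))
        stop(sprintf("option %s needs a value", a), call. = FALSE)
      opts[[substring(a, 3)]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `denitkin` command-line interface
#' (see `inst/scripts/denitkin.R` for the executable wrapper). Every run
#' logs the package version, the parsed configuration and the seed to
#' stderr, writes its outputs as CSV/JSON under `--out`, and returns an
#' exit status instead of throwing: 0 on success, 1 on any validation
#' or usage failure (with a diagnostic on stderr).
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L) { message(cli_usage()); return(invisible(1L)) }
    cmd <- argv[1]
    opts <- cli_opts(argv[-1])
    seed <- as.integer(opts$seed %||% "1")
    out_dir <- opts$out %||% "."
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    message(sprintf("denitkin %s | command: %s | seed: %d | options: %s",
                    utils::packageVersion("denitkin"), cmd, seed,
                    paste(names(opts), unlist(opts), sep = "=",
                          collapse = " ")))
    switch(cmd,
      "fit-all" = {
        tab <- validate_table(req(opts, "input"), "growth")
        fits <- fit_all(tab)
        write_fit_report(fits, file.path(out_dir, "fit_report.csv"))
        jsonlite::write_json(fit_report(fits),
                             file.path(out_dir, "fit_report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      "fit-single" = {
        tab <- validate_table(req(opts, "input"), "growth")
        f <- fit_single(tab, opts$substrate %||% "s1", req(opts, "kind"))
        writeLines(utils::capture.output(print(f)),
                   file.path(out_dir, "fit_single.txt"))
      },
      "fit-double" = {
        tab <- validate_table(req(opts, "input"), "growth")
        f <- fit_double(tab, req(opts, "kind1"), req(opts, "kind2"))
        writeLines(utils::capture.output(print(f)),
                   file.path(out_dir, "fit_double.txt"))
      },
      "arrhenius" = {
        df <- utils::read.csv(req(opts, "input"))
        f <- fit_arrhenius(df$temperature_K, df$mu_max)
        jsonlite::write_json(
          list(A_per_day = f$params$A, E_kJ_mol = f$params$E,
               r_squared = f$r_squared),
          file.path(out_dir, "arrhenius.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
      },
      "metrics" = {
        ts <- validate_table(req(opts, "input"), "batch")
        mets <- do.call(rbind, lapply(
          c("nitrite_accumulation", "nitrate_removal",
            "specific_nitrate_rate", "specific_total_N_rate"),
          function(m) metric_series(ts, m)))
        utils::write.csv(as.data.frame(mets),
                         file.path(out_dir, "metrics.csv"),
                         row.names = FALSE)
      },
      "ddct" = {
        cts <- validate_table(req(opts, "input"), "ct")
        folds <- fold_table(cts, req(opts, "control"))
        utils::write.csv(as.data.frame(folds),
                         file.path(out_dir, "fold_changes.csv"),
                         row.names = FALSE)
      },
      "simulate" = {
        what <- opts$positional[1] %||% "growth"
        switch(what,
          growth = write_dataset(gen_growth_table(
            double_params(0.5523, "andrews", 4.34, 8970.72,
                          "andrews", 48.25, 14194.83),
            mu_sd = as.numeric(opts$mu_sd %||% "0"), seed = seed),
            file.path(out_dir, "growth.csv")),
          batch = write_dataset(gen_batch_series(seed = seed),
                                file.path(out_dir, "batch.csv")),
          ct = write_dataset(gen_ct_table(
            tibble::tibble(condition = "treatment",
                           gene = c("napA", "nirB", "nirD"),
                           fold = c(1.12, 1.33, 1.41)),
            control = "control", seed = seed,
            ct_sd = as.numeric(opts$ct_sd %||% "0")),
            file.path(out_dir, "ct.csv")),
          arrhenius = {
            ser <- gen_arrhenius_series(arrhenius_params(77.48, 13.80),
                                        seed = seed)
            utils::write.csv(as.data.frame(ser),
                             file.path(out_dir, "arrhenius.csv"),
                             row.names = FALSE)
          },
          stop(sprintf("unknown simulate target: %s", what), call. = FALSE))
      },
      stop(sprintf("unknown command: %s\n%s", cmd, cli_usage()),
           call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

req <- function(opts, name) {
  v <- opts[[name]]
  if (is.null(v)) stop(sprintf("--%s is required", name), call. = FALSE)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
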