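#' Parse volume fractions that may carry a percent suffix
#'
#' Composition tables often print volume fractions as percentages
#' ("0.017%"). This parser accepts plain fractions and "%"-suffixed
#' values, returning plain fractions.
#'
#' @param x numeric or character vector.
#' @return Numeric vector of fractions.
#' @examples
#' parse_volume_fraction(c("0.017%", "0.00017"))  # both 1.7e-4
#' @export
parse_volume_fraction <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  val <- suppressWarnings(as.numeric(sub("%$", "", x)))
  if (anyNA(val))
    stop("unparseable volume fraction value(s): ",
         paste(x[is.na(val)], collapse = ", "), call. = FALSE)
  ifelse(pct, val / 100, val)
}

#' Read a delimited-text table with schema validation
#'
#' Strict CSV dialect: comma-separated, header row, UTF-8, "." decimal.
#' Extra columns are tolerated; missing required columns and unparseable
#' numeric cells raise errors naming the offending column (and row).
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @param numeric_cols columns to be coerced to numeric (errors report the
#'   first bad row); columns named `phi` are run through
#'   [parse_volume_fraction()] first.
#' @return data.frame with an attribute `source_path`.
#' @export
read_table <- function(path, required = character(),
                       numeric_cols = required) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- if (identical(col, "phi")) {
      tryCatch(parse_volume_fraction(raw), error = function(e)
        stop("column 'phi' in ", path, ": ", conditionMessage(e),
             call. = FALSE))
    } else suppressWarnings(as.numeric(raw))
    if (anyNA(val) && !anyNA(raw)) {
      bad <- which(is.na(val))[1]
      stop("unparseable numeric value '", raw[bad], "' at row ", bad,
           ", column '", col, "' of ", path, call. = FALSE)
    }
    df[[col]] <- val
  }
  attr(df, "source_path") <- path
  df
}

#' Read a phase-composition table
#'
#' Expects columns `system_id`, `c_tot_uM`, `c_dil_uM`, `phi` (the latter
#' may be "%"-suffixed). Derived columns `c_dense_uM`, `K_E` and
#' `fraction_dense` are appended.
#'
#' @param path CSV file path.
#' @return data.frame with measured and derived columns.
#' @export
read_phase_compositions <- function(path) {
  df <- read_table(path, required = c("system_id", "c_tot_uM", "c_dil_uM",
                                      "phi"),
                   numeric_cols = c("c_tot_uM", "c_dil_uM", "phi"))
  comps <- lapply(seq_len(nrow(df)), function(i)
    phase_composition(df$c_tot_uM[i], df$c_dil_uM[i], df$phi[i]))
  df$c_dense_uM <- vapply(comps, `[[`, 0, "c_dense")
  df$K_E <- vapply(comps, `[[`, 0, "K_E")
  df$fraction_dense <- vapply(comps, `[[`, 0, "fraction_dense")
  df
}

#' Write a table in the package's strict CSV dialect
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Read progress curves from long-format delimited text
#'
#' Expects columns `replicate_id`, `condition_label`, `time_s`, `signal`,
#' plus per-curve constants `substrate_0_uM` and `enzyme_0_uM`.
#'
#' @param path CSV file path.
#' @return A list of [progress_curve()] objects (one per
#'   replicate/condition/substrate combination).
#' @export
read_progress_curves <- function(path) {
  df <- read_table(path,
                   required = c("replicate_id", "condition_label", "time_s",
                                "signal", "substrate_0_uM", "enzyme_0_uM"),
                   numeric_cols = c("time_s", "signal", "substrate_0_uM",
                                    "enzyme_0_uM"))
  key <- interaction(df$replicate_id, df$condition_label,
                     df$substrate_0_uM, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_s), ]
    progress_curve(d$time_s, d$signal, d$substrate_0_uM[1],
                   d$enzyme_0_uM[1], d$condition_label[1],
                   d$replicate_id[1])
  })
}

#' Run the full condensate-kinetics analysis pipeline
#'
#' Chains the analysis stages on user-supplied (or synthetic) tables:
#' phase-composition mass balance, Michaelis-Menten fitting of initial
#' rates, the two-phase rate-ratio fit with product-localization curve and
#' transport diagnostics, and ratiometric pH estimation. Each stage is
#' driven by one block of the configuration list; stages without a block
#' are skipped. Every defaulted parameter is echoed into the returned
#' report, and all randomness flows from `config$seed`.
#'
#' @param config a list with optional blocks:
#'   \describe{
#'     \item{`partitioning`}{`list(data=|path=)` phase-composition table
#'       (see [read_phase_compositions()]).}
#'     \item{`mm`}{`list(data=|path=, enzyme_0=)` initial-rate table with
#'       columns `S_uM`, `rate`, optionally `rate_se`.}
#'     \item{`two_phase`}{`list(data=|path=, phi_D=, K_E=, kcat_I=, KM_I=,
#'       K_S=1, use_equilibrium_closure=TRUE, D=, diameter=, S_grid=)`
#'       ratio table plus known constants; `D`/`diameter` trigger
#'       transport diagnostics.}
#'     \item{`ph`}{`list(calibration=|calibration_path=,
#'       measurements=|measurements_path=)` SNARF tables (columns
#'       `pH`, `ratio` and `pH_nominal`, `phase`, `ratio`).}
#'   }
#'   plus `seed` (default 1) and optional `out_dir`.
#' @return A `pipeline_report` list with one element per executed stage;
#'   written as CSV/text files under `out_dir` when given.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  stages <- intersect(c("partitioning", "mm", "two_phase", "ph"),
                      names(config))
  if (!length(stages))
    stop("config selects no stages: provide at least one of ",
         "'partitioning', 'mm', 'two_phase', 'ph'", call. = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  report <- list(seed = seed, stages = stages)

  get_data <- function(block, reader = NULL, what = "data") {
    if (!is.null(block[[what]])) return(block[[what]])
    path_key <- if (what == "data") "path" else paste0(what, "_path")
    if (!is.null(block[[path_key]])) {
      if (is.null(reader)) return(read_table(block[[path_key]]))
      return(reader(block[[path_key]]))
    }
    stop("stage block provides neither '", what, "' nor '", path_key, "'",
         call. = FALSE)
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("partitioning" %in% stages) {
    report$partitioning <- run_stage("partitioning", function() {
      blk <- config$partitioning
      df <- if (!is.null(blk$data)) {
        d <- blk$data
        d$phi <- parse_volume_fraction(d$phi)
        comps <- lapply(seq_len(nrow(d)), function(i)
          phase_composition(d$c_tot_uM[i], d$c_dil_uM[i], d$phi[i]))
        d$c_dense_uM <- vapply(comps, `[[`, 0, "c_dense")
        d$K_E <- vapply(comps, `[[`, 0, "K_E")
        d$fraction_dense <- vapply(comps, `[[`, 0, "fraction_dense")
        d
      } else read_phase_compositions(blk$path)
      df
    })
  }

  if ("mm" %in% stages) {
    report$mm <- run_stage("mm", function() {
      blk <- config$mm
      rates <- get_data(blk)
      if (is.null(blk$enzyme_0))
        stop("mm block needs enzyme_0 (uM)", call. = FALSE)
      fit_michaelis_menten(rates, blk$enzyme_0)
    })
  }

  if ("two_phase" %in% stages) {
    report$two_phase <- run_stage("two_phase", function() {
      blk <- config$two_phase
      ratios <- get_data(blk)
      defaults <- list(K_S = 1, use_equilibrium_closure = TRUE,
                       S_grid = seq(0, 1000, by = 10))
      for (nm in names(defaults))
        if (is.null(blk[[nm]])) blk[[nm]] <- defaults[[nm]]
      fit <- fit_dense_phase_constants(
        ratios, phi_D = blk$phi_D, K_E = blk$K_E, kcat_I = blk$kcat_I,
        KM_I = blk$KM_I, K_S = blk$K_S,
        use_equilibrium_closure = blk$use_equilibrium_closure)
      out <- list(fit = fit, defaults_used = defaults)
      if (!isTRUE(fit$non_identifiable)) {
        out$dense_fraction_curve <- data.frame(
          S_uM = blk$S_grid,
          fraction_product_dense = fraction_product_dense(fit$params,
                                                          blk$S_grid))
        if (!is.null(blk$D) && !is.null(blk$diameter))
          out$transport <- transport_diagnostics(blk$D, blk$diameter,
                                                 fit$kcat_II)
      }
      out
    })
  }

  if ("ph" %in% stages) {
    report$ph <- run_stage("ph", function() {
      blk <- config$ph
      cal_data <- get_data(blk, what = "calibration")
      cal <- fit_snarf_calibration(cal_data)
      out <- list(calibration = cal)
      meas <- tryCatch(get_data(blk, what = "measurements"),
                       error = function(e) NULL)
      if (!is.null(meas)) {
        est <- ratio_to_ph(cal, meas$ratio)
        meas$pH_apparent <- est$pH
        meas$flag <- est$flag
        ok <- est$flag != "unresolvable"
        out$measurements <- meas
        out$shift <- ph_shift(meas$pH_apparent[meas$phase == "dense" & ok],
                              meas$pH_apparent[meas$phase == "dilute" & ok])
      }
      out
    })
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

# serialize the report as plain-text artifacts with a provenance header
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# phasekin %s | seed %s",
                 as.character(utils::packageVersion("phasekin")),
                 report$seed)
  lines <- c(hdr, paste0("# stages: ", paste(report$stages, collapse = ", ")))
  if (!is.null(report$partitioning)) {
    write_table(report$partitioning,
                file.path(out_dir, "phase_compositions.csv"))
    lines <- c(lines, "", "[partitioning] written: phase_compositions.csv")
  }
  if (!is.null(report$mm)) {
    p <- report$mm
    lines <- c(lines, "", "[mm] Michaelis-Menten fit",
               sprintf("v_max = %.6g +/- %.3g uM/s", p$v_max, p$v_max_se),
               sprintf("K_M = %.6g +/- %.3g uM", p$K_M, p$K_M_se),
               sprintf("k_cat = %.6g 1/s", p$k_cat))
  }
  if (!is.null(report$two_phase) &&
      !isTRUE(report$two_phase$fit$non_identifiable)) {
    f <- report$two_phase$fit
    lines <- c(lines, "", "[two_phase] dense-phase constants",
               sprintf("kcat_II = %.6g +/- %.3g 1/s", f$kcat_II,
                       f$kcat_II_se),
               sprintf("KM_eff_II = %.6g +/- %.3g uM", f$KM_eff_II,
                       f$KM_eff_II_se))
    if (!is.null(report$two_phase$dense_fraction_curve))
      write_table(report$two_phase$dense_fraction_curve,
                  file.path(out_dir, "dense_fraction_curve.csv"))
    if (!is.null(report$two_phase$transport))
      lines <- c(lines, sprintf("tau_diff = %.4g s, t_react = %.4g s (%s)",
                                report$two_phase$transport$tau_diff,
                                report$two_phase$transport$t_react,
                                report$two_phase$transport$verdict))
  }
  if (!is.null(report$ph)) {
    cal <- report$ph$calibration
    lines <- c(lines, "", "[ph] SNARF calibration",
               sprintf("pKa_app = %.3f, R_acid = %.4g, R_base = %.4g",
                       cal$pKa_app, cal$R_acid, cal$R_base))
    if (!is.null(report$ph$shift))
      lines <- c(lines, sprintf("dense - dilute pH shift = %+.2f +/- %.2f",
                                report$ph$shift$shift, report$ph$shift$se))
    if (!is.null(report$ph$measurements))
      write_table(report$ph$measurements,
                  file.path(out_dir, "ph_measurements.csv"))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("phasekin pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("stages run:", paste(x$stages, collapse = ", "), "\n")
  invisible(x)
}
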