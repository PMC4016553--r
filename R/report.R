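#' Read a scenario from a YAML or JSON config file
#'
#' Accepts a flat key-value file with keys `alpha0`, `alpha1`, `delta1`,
#' `delta2`, `lambda`, `T`, `N`, `F`, `S_M`, and optionally `s0` and a
#' `bias` block (`type` plus the arguments of [policy_bias()]). Unknown keys
#' are an error, as is any invalid value — the offending key is named.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [hcc_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  # YAML 1.1 reads bare keys N and T as booleans; map them back
  names(cfg)[names(cfg) == "FALSE"] <- "N"
  names(cfg)[names(cfg) == "TRUE"] <- "T"
  scenario_from_list(cfg)
}

#' @rdname read_scenario
#' @param cfg A named list with the same keys as the config file.
#' @export
scenario_from_list <- function(cfg) {
  allowed <- c("alpha0", "alpha1", "delta1", "delta2", "lambda", "T",
               "N", "F", "S_M", "s0", "bias")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  g <- NULL
  if (!is.null(cfg$bias)) {
    b <- cfg$bias
    g <- policy_bias(type = b$type,
                     value = b$value %||% 1, at = b$at %||% 5,
                     breaks = unlist(b$breaks), values = unlist(b$values))
  }
  args <- cfg[setdiff(names(cfg), "bias")]
  do.call(hcc_scenario, c(args, list(g = g)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario end to end and write its outputs
#'
#' Programmatic driver behind the `hcc-alloc` command line: executes the
#' requested actions and writes machine-readable outputs, each echoing the
#' full parameter record and the package version in its header.
#'
#' Actions and their outputs (written under `out_dir`):
#' \describe{
#'   \item{`curve`}{`curve.csv` — columns `s0, deaths, survivors,
#'     grafts_used`, parameters in leading `#` comment lines.}
#'   \item{`optimize`}{`optimize.json` — `s_star`, `M_star`, `s_eq`,
#'     `M_ref` (mortality at the Milan cutoff), `boundary`, parameter echo.}
#'   \item{`milan`}{`milan.json` — the four Milan proportions, the branch
#'     taken, the full-utilization threshold and expected grafts used.}
#'   \item{`simulate`}{`cohort.csv` (per patient: `size_cm, transplanted,
#'     death_time_years`) and `replicates.csv` (per replicate death counts);
#'     uses `seed` and `reps`.}
#'   \item{`fit`}{`fit.json` — exponential fit of the sizes in `sizes_file`
#'     (single-column CSV or plain list, header optional).}
#' }
#'
#' @param scn An [hcc_scenario()], or a path to a config file for
#'   [read_scenario()].
#' @param actions Character vector from `c("curve", "optimize", "milan",
#'   "simulate", "fit")`.
#' @param out_dir Output directory, created if missing.
#' @param seed Integer seed for the stochastic actions.
#' @param reps Replicates for `simulate`.
#' @param thresholds Grid for `curve`/`optimize`.
#' @param sizes_file Input sizes for `fit`.
#' @param plot If `TRUE`, also writes `curve.pdf` alongside `curve.csv`.
#' @return Invisibly, a named list of the paths written.
#' @examples
#' dir <- tempfile()
#' run_scenario(hcc_scenario(), actions = "milan", out_dir = dir)
#' @export
run_scenario <- function(scn, actions = c("curve", "optimize"),
                         out_dir = ".", seed = 1L, reps = 100L,
                         thresholds = seq(0, 15, by = 0.01),
                         sizes_file = NULL, plot = FALSE) {
  if (is.character(scn)) scn <- read_scenario(scn)
  stopifnot(inherits(scn, "hcc_scenario"))
  actions <- match.arg(actions,
                       c("curve", "optimize", "milan", "simulate", "fit"),
                       several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  echo <- as.list(scenario_record(scn))
  version <- as.character(utils::packageVersion("hccalloc"))
  paths <- list()

  for (act in actions) {
    if (act == "curve") {
      crv <- mortality_curve(scn, thresholds)
      f <- file.path(out_dir, "curve.csv")
      write_csv_header(f, echo, version)
      tab <- as.data.frame(lapply(as.data.frame(crv), fmt_num))
      suppressWarnings(utils::write.table(
        tab, f, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
      paths$curve <- f
      if (plot) {
        pf <- file.path(out_dir, "curve.pdf")
        grDevices::pdf(pf, width = 6, height = 4)
        plot(crv)
        grDevices::dev.off()
        paths$curve_plot <- pf
      }
    } else if (act == "optimize") {
      opt <- optimal_threshold(scn, thresholds)
      eqv <- equivalent_threshold(scn)
      f <- file.path(out_dir, "optimize.json")
      jsonlite::write_json(
        list(s_star = opt$s_star, M_star = opt$M_star,
             boundary = opt$boundary,
             s_eq = eqv$s_eq, M_eq = eqv$M_eq, M_ref = eqv$M_ref,
             params = echo, version = version),
        f, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
      paths$optimize <- f
    } else if (act == "milan") {
      ms <- milan_summary(scn)
      f <- file.path(out_dir, "milan.json")
      jsonlite::write_json(
        list(p_nt_below = ms$p_nt_below, p_t_below = ms$p_t_below,
             p_nt_above = ms$p_nt_above, p_t_above = ms$p_t_above,
             branch = ms$branch,
             s_F = full_utilization_threshold(scn),
             grafts_used = grafts_used(scn),
             params = echo, version = version),
        f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      paths$milan <- f
    } else if (act == "simulate") {
      coh <- simulate.hcc_scenario(scn, nsim = 1, seed = seed)
      f <- file.path(out_dir, "cohort.csv")
      write_csv_header(f, echo, version, seed = seed)
      tab <- data.frame(size_cm = fmt_num(coh$size_cm),
                        transplanted = as.integer(coh$transplanted),
                        death_time_years = fmt_num(coh$death_time_years))
      suppressWarnings(utils::write.table(
        tab, f, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
      paths$cohort <- f
      mc <- mc_mortality(scn, reps = reps, seed = seed)
      f2 <- file.path(out_dir, "replicates.csv")
      write_csv_header(f2, echo, version, seed = seed)
      suppressWarnings(utils::write.table(
        data.frame(replicate = seq_len(reps), deaths = mc$deaths),
        f2, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
      paths$replicates <- f2
    } else if (act == "fit") {
      if (is.null(sizes_file))
        stop("'fit' needs 'sizes_file'", call. = FALSE)
      sizes <- read_sizes(sizes_file)
      ft <- fit_tumor_sizes(sizes)
      f <- file.path(out_dir, "fit.json")
      jsonlite::write_json(
        list(lambda_hat = ft$lambda_hat, mean_hat = ft$mean_hat,
             ci95 = ft$ci95, ci95_rounded_mean = ft$ci95_rounded_mean,
             n = ft$n, r_squared = ft$r_squared,
             params = echo, version = version),
        f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      paths$fit <- f
    }
  }
  invisible(paths)
}

# Single-column CSV (optional header) or whitespace-separated plain list.
read_sizes <- function(path) {
  if (!file.exists(path)) stop("sizes file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(lines, "[,;[:space:]]+"))))
  if (length(vals) && is.na(vals[1])) vals <- vals[-1]  # header token
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no numeric sizes found in ", path, call. = FALSE)
  vals
}

write_csv_header <- function(path, echo, version, seed = NULL) {
  hdr <- c(sprintf("# hccalloc %s", version),
           sprintf("# %s=%s", names(echo),
                   vapply(echo, fmt_num, "")),
           if (!is.null(seed)) sprintf("# seed=%s", seed))
  writeLines(hdr, path)
}

# Fixed-format numbers so identical runs give byte-identical files.
fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
}
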