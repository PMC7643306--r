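#' Configuration for a futility-boundary planning report
#'
#' Validates the parameters driving [run_report].  Exactly one of `power`
#' and `n_total` must be supplied; `n_total` may be a vector to compare
#' several sample-size settings side by side (as is common when contrasting
#' a 90%- and an 80%-powered plan).
#'
#' @param delta anticipated standardized effect.
#' @param alpha one-sided global significance level.
#' @param power target fixed-design power used to derive the sample size.
#' @param n_total total sample size(s), each split equally over two arms.
#' @param info_fraction interim information fraction, in (0, 1).
#' @param pow_loss,pi_wrong admissible parameter values for the sensitivity
#'   table (vectors; may be empty to skip the table).
#' @param effects true effects for the correct-stopping columns; `NULL` for
#'   the default `c(delta/2, 0)`.
#' @param simulate logical: append Monte-Carlo cross-check columns.
#' @param reps,seed Monte-Carlo replicates per setting and master seed.
#' @param out output path prefix; files `<out>_design`, `<out>_table`,
#'   `<out>_grid` (and `<out>_mc`) are written with the format's extension.
#'   `NULL` prints to the console and writes nothing.
#' @param format `"csv"`, `"tsv"` or `"text"` (pretty tables, 2 decimals).
#' @param grid logical: write the dense `(pow_loss, pi_wrong)` boundary grid
#'   used for sensitivity plots.
#' @param quiet suppress progress messages.
#' @return a validated list of class `"gs_run_config"`.
#' @examples
#' cfg <- run_config(delta = 0.5, alpha = 0.025, n_total = c(188, 140),
#'                   pow_loss = c(0.01, 0.05), pi_wrong = c(0.01, 0.05, 0.10),
#'                   out = NULL)
#' @export
run_config <- function(delta, alpha = 0.025, power = NULL, n_total = NULL,
                       info_fraction = 0.5,
                       pow_loss = numeric(0), pi_wrong = numeric(0),
                       effects = NULL, simulate = FALSE, reps = 1e5,
                       seed = 1L, out = NULL, format = "csv",
                       grid = FALSE, quiet = FALSE) {
  fail <- function(key, msg) stop("config key '", key, "': ", msg, call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    fail("delta", "must be a single positive number")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5)
    fail("alpha", "must lie in (0, 0.5)")
  if (is.null(power) == is.null(n_total))
    fail("power/n_total", "exactly one of the two must be given")
  if (!is.null(n_total)) {
    if (!is.numeric(n_total) || any(n_total != round(n_total)) ||
        any(n_total %% 2 != 0) || any(n_total < 4))
      fail("n_total", "must be even integers >= 4 (equal allocation)")
  } else if (!is.numeric(power) || power <= alpha || power >= 1) {
    fail("power", "must lie in (alpha, 1)")
  }
  if (!is.numeric(info_fraction) || info_fraction <= 0 || info_fraction >= 1)
    fail("info_fraction", "must lie in (0, 1)")
  if (length(pow_loss) > 0 &&
      (!is.numeric(pow_loss) || any(pow_loss <= 0 | pow_loss >= 1)))
    fail("pow_loss", "values must lie in (0, 1)")
  if (length(pi_wrong) > 0 &&
      (!is.numeric(pi_wrong) || any(pi_wrong < 0 | pi_wrong > 1)))
    fail("pi_wrong", "values must lie in [0, 1]")
  if (!is.null(effects) && !is.numeric(effects))
    fail("effects", "must be numeric")
  if (!isTRUE(simulate) && !isFALSE(simulate))
    fail("simulate", "must be TRUE or FALSE")
  if (!is.numeric(reps) || reps < 1) fail("reps", "must be >= 1")
  if (!is.numeric(seed) || seed != round(seed)) fail("seed", "must be an integer")
  if (!is.character(format) || !format %in% c("csv", "tsv", "text"))
    fail("format", "must be one of csv, tsv, text")
  structure(list(delta = delta, alpha = alpha, power = power,
                 n_total = n_total, info_fraction = info_fraction,
                 pow_loss = pow_loss, pi_wrong = pi_wrong, effects = effects,
                 simulate = simulate, reps = as.integer(reps),
                 seed = as.integer(seed), out = out, format = format,
                 grid = isTRUE(grid), quiet = isTRUE(quiet)),
            class = "gs_run_config")
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; list-valued keys
#' (`n_total`, `pow_loss`, `pi_wrong`, `effects`) take comma-separated
#' values.  Keys mirror the arguments of [run_config].
#'
#' @param path file path.
#' @return a named list suitable for `do.call(run_config, ...)`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  numeric_keys <- c("delta", "alpha", "power", "n_total", "info_fraction",
                    "pow_loss", "pi_wrong", "effects", "reps", "seed")
  logical_keys <- c("simulate", "grid", "quiet")
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config line is not 'key = value': ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parsed <- if (key %in% numeric_keys) {
      v <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (anyNA(v)) stop("config key '", key, "': not numeric: ", val,
                         call. = FALSE)
      v
    } else if (key %in% logical_keys) {
      toupper(val) %in% c("TRUE", "T", "YES", "1")
    } else if (key %in% c("out", "format")) {
      val
    } else stop("config key '", key, "': unknown key", call. = FALSE)
    out[[key]] <- parsed
  }
  out
}

#' Run the full planning report
#'
#' Drives the whole analysis for a configuration: builds the design(s),
#' writes a design summary (sample sizes, local levels, power without a
#' futility rule), the sensitivity table of optimal boundaries and operating
#' characteristics over the admissible-parameter grid, optionally Monte-Carlo
#' cross-check estimates with standard errors, and optionally a dense
#' boundary grid for plotting.  All output is deterministic for a fixed
#' configuration (simulation sections use seeds derived from `seed`).
#'
#' @param config a [run_config] object (or plain list of its arguments).
#' @return invisibly, a list with elements `design_summary`, `table`, `mc`
#'   and `grid` (data frames; `NULL` where not requested).
#' @examples
#' cfg <- run_config(delta = 0.5, alpha = 0.025, n_total = 188,
#'                   pow_loss = 0.05, pi_wrong = 0.05, out = NULL,
#'                   quiet = TRUE)
#' rep <- run_report(cfg)
#' rep$table
#' @export
run_report <- function(config) {
  if (!inherits(config, "gs_run_config")) config <- do.call(run_config, config)
  say <- function(...) if (!config$quiet) message(...)
  say("gsfutility ", as.character(utils::packageVersion("gsfutility")),
      " | delta=", config$delta, " alpha=", config$alpha,
      " info_fraction=", config$info_fraction)

  designs <- if (!is.null(config$n_total)) {
    lapply(config$n_total, function(N)
      gs_design(config$delta, config$alpha, n_per_group = N / 2,
                info_fraction = config$info_fraction))
  } else {
    list(gs_design(config$delta, config$alpha, power = config$power,
                   info_fraction = config$info_fraction))
  }

  design_summary <- do.call(rbind, lapply(designs, function(d) data.frame(
    n_total = d$n_total, n_per_group = d$n_per_group,
    n1_per_group = d$n1_per_group, alpha1 = d$alpha1, alpha12 = d$alpha12,
    corr = d$rho,
    power_no_futility = overall_power(d, "none", d$delta))))

  have_grid <- length(config$pow_loss) > 0 && length(config$pi_wrong) > 0
  tab <- if (have_grid)
    sensitivity_grid(designs, config$pow_loss, config$pi_wrong,
                     true_effects = config$effects) else NULL

  mc <- NULL
  if (config$simulate && have_grid) {
    say("Monte-Carlo cross-check: ", config$reps, " replicates per setting")
    mc_rows <- lapply(seq_len(nrow(tab)), function(i) {
      d <- designs[[match(tab$n_total[i],
                          vapply(designs, `[[`, integer(1), "n_total"))]]
      eff <- if (is.null(config$effects)) c(d$delta / 2, 0) else config$effects
      oc <- estimate_operating_characteristics(
        d, tab$alpha0_opt[i], effects = c(d$delta, eff),
        n_reps = config$reps, seed = config$seed + 100L * (i - 1L))
      data.frame(row = i, n_total = tab$n_total[i],
                 alpha0_opt = tab$alpha0_opt[i],
                 mc_power = oc$power[1], se_power = oc$se_power[1],
                 mc_wrong_stop = oc$p_futility_stop[1],
                 se_wrong_stop = oc$se_futility_stop[1])
    })
    mc <- do.call(rbind, mc_rows)
  }

  dense <- NULL
  if (config$grid && length(config$pow_loss) > 0) {
    dense <- sensitivity_grid(designs, config$pow_loss,
                              pi_wrong_values = seq(0.01, 0.30, by = 0.01))
    dense <- dense[, c("n_total", "pow_loss", "pi_wrong", "alpha0_opt")]
  }

  .write_report(config, design_summary, tab, mc, dense, say)
  invisible(list(design_summary = design_summary, table = tab, mc = mc,
                 grid = dense))
}

.write_report <- function(config, design_summary, tab, mc, dense, say) {
  fmt_num <- function(df) {
    if (is.null(df)) return(NULL)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 4))
    df
  }
  if (is.null(config$out)) {
    .print_pretty(design_summary, tab, mc, dense)
    return(invisible(NULL))
  }
  pieces <- list(design = design_summary, table = tab, mc = mc, grid = dense)
  ext <- switch(config$format, csv = ".csv", tsv = ".tsv", text = ".txt")
  for (nm in names(pieces)) {
    df <- pieces[[nm]]
    if (is.null(df)) next
    path <- paste0(config$out, "_", nm, ext)
    if (config$format == "text") {
      con <- file(path, "w")
      sink(con)
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) round2(x, 2))
      print(df, row.names = FALSE)
      sink()
      close(con)
    } else {
      utils::write.table(fmt_num(df), path, sep = if (config$format == "csv")
        "," else "\t", row.names = FALSE, quote = FALSE, dec = ".",
        fileEncoding = "UTF-8")
    }
    say("wrote ", path)
  }
}

.print_pretty <- function(design_summary, tab, mc, dense) {
  cat("Design summary\n")
  print(design_summary, row.names = FALSE, digits = 4)
  if (!is.null(tab)) {
    cat("\nOptimal futility boundaries and operating characteristics\n")
    t2 <- tab
    num <- vapply(t2, is.numeric, logical(1)) &
      !names(t2) %in% c("n_total", "pow_loss", "pi_wrong")
    t2[num] <- lapply(t2[num], round2, 2)
    print(t2, row.names = FALSE)
  }
  if (!is.null(mc)) {
    cat("\nMonte-Carlo cross-check\n")
    print(mc, row.names = FALSE, digits = 4)
  }
  invisible(NULL)
}

#' Round half away from zero
#'
#' Presentation rounding used in pretty tables (0.218 -> 0.22, 0.125 -> 0.13),
#' as opposed to [base::round]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round2 <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
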