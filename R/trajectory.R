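#' @export
print.gf_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("Glomerular fibrosis trajectory:",
      sprintf("%.1f-%.1f weeks, %d grid points\n",
              min(x$time_weeks), max(x$time_weeks), nrow(x)))
  if (!is.null(sc)) cat("  scenario:", format_scenario(sc), "\n")
  flags <- attr(x, "at_steady_state")
  if (!is.null(flags))
    cat("  at steady state at horizon:",
        paste(names(flags)[flags], collapse = ", "),
        if (any(!flags)) paste0("(not: ", paste(names(flags)[!flags],
                                                collapse = ", "), ")"), "\n")
  print(utils::head(as.data.frame(x)[, c("time_weeks", "glucose", GF_SPECIES)], 4))
  cat("  ...\n")
  invisible(x)
}

#' @export
summary.gf_trajectory <- function(object, ...) {
  df <- as.data.frame(object)
  rng <- t(vapply(GF_SPECIES, function(sp) range(df[[sp]]), numeric(2)))
  colnames(rng) <- c("min", "max")
  final <- vapply(GF_SPECIES, function(sp) df[[sp]][nrow(df)], numeric(1))
  out <- list(window_weeks = range(df$time_weeks),
              range = rng, final = final,
              at_steady_state = attr(object, "at_steady_state"),
              scenario = attr(object, "scenario"))
  class(out) <- "summary.gf_trajectory"
  out
}

#' @export
print.summary.gf_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory over %.1f-%.1f weeks\n",
              x$window_weeks[1], x$window_weeks[2]))
  if (!is.null(x$scenario)) cat("scenario:", format_scenario(x$scenario), "\n")
  df <- data.frame(final = signif(x$final, 4),
                   min = signif(x$range[, "min"], 4),
                   max = signif(x$range[, "max"], 4),
                   steady = x$at_steady_state[GF_SPECIES])
  print(df)
  invisible(x)
}

#' @export
plot.gf_trajectory <- function(x, species = GF_SPECIES, log = "y", ...) {
  df <- as.data.frame(x)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(species) + 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(df$time_weeks, df$glucose, type = "l", xlab = "weeks",
                 ylab = "g/mL", main = "glucose input")
  for (sp in species)
    graphics::plot(df$time_weeks, df[[sp]], type = "l", log = log,
                   xlab = "weeks", ylab = "g/mL", main = sp)
  invisible(x)
}

#' Write and read trajectories as CSV
#'
#' Column layout is fixed: `time_weeks,glucose,AGE,MCP,MAC,TGF,AMC,MMP,TIMP,COL`
#' with concentrations in g/mL at full double precision.
#'
#' @param traj a `gf_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a data frame with the same columns.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("time_weeks", "glucose", GF_SPECIES)]
  ## format() at 17 significant digits keeps the round trip bit-faithful
  fmt <- as.data.frame(lapply(df, function(col) format(col, digits = 17,
                                                       scientific = TRUE,
                                                       trim = TRUE)))
  names(fmt) <- names(df)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_weeks", "glucose", GF_SPECIES)
  if (!all(need %in% names(df)))
    stop("trajectory file is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}

## linear interpolation of one species at arbitrary week values
traj_at <- function(traj, species, weeks) {
  stats::approx(traj$time_weeks, traj[[species]], xout = weeks, rule = 2)$y
}
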