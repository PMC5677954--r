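#' Cytokine treatment schedule
#'
#' An ordered list of cytokine delivery events. Scenario labels follow the
#' field's convention: cytokine initial plus delivery day, so `"B1I4"` means
#' BMP-2 delivered at day 1 and IGF-1 at day 4.
#'
#' @param cytokine Character vector, each `"BMP2"` or `"IGF1"`.
#' @param day Integer vector of delivery days (>= 0).
#' @param dose Numeric vector of doses in ng/ml (> 0); default 50 ng/ml, the
#'   standard experimental dose. Recycled to the number of events.
#' @param scenario Scenario label; derived from the events when `NULL`.
#' @return An object of class `treatment_schedule` with fields `events`
#'   (data.frame `cytokine`, `day`, `dose`, sorted by day) and `scenario`.
#' @examples
#' treatment_schedule(c("BMP2", "IGF1"), c(1, 4))  # the B1I4 scenario
#' @export
treatment_schedule <- function(cytokine = character(0), day = integer(0),
                               dose = 50, scenario = NULL) {
  stopifnot(length(cytokine) == length(day))
  if (length(cytokine)) {
    if (!all(cytokine %in% c("BMP2", "IGF1")))
      stop("cytokine must be 'BMP2' or 'IGF1'")
    if (any(day < 0)) stop("delivery day must be >= 0")
    dose <- rep_len(dose, length(cytokine))
    if (any(dose <= 0)) stop("dose must be > 0")
  } else {
    dose <- numeric(0)
  }
  events <- data.frame(cytokine = cytokine, day = as.numeric(day), dose = dose,
                       stringsAsFactors = FALSE)
  events <- events[order(events$day, events$cytokine), , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(scenario)) {
    scenario <- if (!nrow(events)) "control" else
      paste0(ifelse(events$cytokine == "BMP2", "B", "I"), events$day,
             collapse = "")
  }
  structure(list(events = events, scenario = scenario),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat("Treatment schedule '", x$scenario, "': ", sep = "")
  if (!nrow(x$events)) {
    cat("no cytokine delivered\n")
  } else {
    cat(paste0(x$events$cytokine, " at day ", x$events$day, " (",
               x$events$dose, " ng/ml)", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read/write a treatment schedule as CSV
#'
#' Columns: `cytokine`, `day`, `dose_ng_per_ml`.
#'
#' @param schedule A `treatment_schedule`.
#' @param path File path.
#' @param scenario Optional scenario label for `read_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  df <- schedule$events
  names(df) <- c("cytokine", "day", "dose_ng_per_ml")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, scenario = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  treatment_schedule(df$cytokine, df$day, df$dose_ng_per_ml, scenario = scenario)
}

# Ligand concentration (arbitrary units, standard 50 ng/ml dose == 1) at time
# t_h (hours) under a schedule: step input switched on at the delivery day and
# held (optional exponential decay, per hour, default off).
ligand_levels <- function(schedule, t_h, ref_dose = 50, decay = 0) {
  out <- c(BMP2 = 0, IGF1 = 0)
  ev <- schedule$events
  for (i in seq_len(nrow(ev))) {
    t_on <- ev$day[i] * 24
    if (t_h >= t_on) {
      amp <- ev$dose[i] / ref_dose
      if (decay > 0) amp <- amp * exp(-decay * (t_h - t_on))
      out[[ev$cytokine[i]]] <- out[[ev$cytokine[i]]] + amp
    }
  }
  out
}
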