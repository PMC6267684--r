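#' Concentration-time profile
#'
#' One mean concentration-time curve for a single (study arm, matrix, route,
#' dose) combination, as produced by a serial-sacrifice design where every
#' time point is the mean over `n` destructively sampled animals.
#'
#' @param arm_id Study-arm identifier.
#' @param matrix One of `"plasma"`, `"tumor"`, `"spleen"`, `"liver"`.
#' @param regimen A [dose_regimen()].
#' @param data A data.frame with columns `time` (h, strictly increasing),
#'   `conc` (ng/mL or ng/g; `NA` allowed only where `blq` is `TRUE`),
#'   `blq` (logical), `n` (animals per time point).
#' @param analyte Optional [analyte_spec()] attached to the profile.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(arm_id, matrix, regimen, data, analyte = NULL) {
  stopifnot(is.character(arm_id), length(arm_id) == 1L,
            inherits(regimen, "dose_regimen"), is.data.frame(data))
  matrix <- match.arg(matrix, c("plasma", "tumor", "spleen", "liver"))
  if (!is.null(analyte)) stopifnot(inherits(analyte, "analyte_spec"))
  need <- c("time", "conc", "blq")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("profile data lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"n" %in% names(data)) data$n <- NA_integer_
  data <- data[c("time", "conc", "blq", "n")]
  data$blq <- as.logical(data$blq)
  if (nrow(data) == 0L) stop("empty profile")
  if (any(data$time < 0)) stop("negative time in profile '", arm_id, "'")
  if (is.unsorted(data$time, strictly = TRUE)) {
    stop("times must be strictly increasing within a profile (arm '",
         arm_id, "', matrix '", matrix, "')")
  }
  bad <- !data$blq & (is.na(data$conc) | data$conc < 0)
  if (any(bad)) {
    stop("negative or missing concentration in non-BLQ record(s) at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  data$conc[data$blq] <- NA_real_   # BLQ records carry no numeric value
  structure(list(arm_id = arm_id, matrix = matrix, regimen = regimen,
                 analyte = analyte, unit = matrix_unit(matrix), data = data),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> arm '%s', %s (%s), %s %g mg/kg, %d time points\n",
              x$arm_id, x$matrix, x$unit, x$regimen$route,
              x$regimen$dose_level, nrow(x$data)))
  print(x$data, row.names = FALSE)
  invisible(x)
}

profile_key <- function(p) paste(p$arm_id, p$matrix, sep = "/")

#' Read concentration-time profiles from a delimited file
#'
#' Expects a CSV with header columns `arm, matrix, route, dose_mg_per_kg,
#' time_h, conc, blq, n` and returns one [conc_profile()] per (arm, matrix)
#' group, time-sorted. Times are in hours; a `time_min` column, if present
#' instead of `time_h`, is converted to hours on read. A BLQ record is a row
#' with `blq = 1` and an empty concentration field. If an `analyte` is given,
#' rows whose concentration falls below the matrix LLOQ but are not flagged
#' BLQ are auto-flagged with a warning.
#'
#' @param source Path to a delimited text file (or a connection).
#' @param analyte Optional [analyte_spec()] used for LLOQ auto-flagging.
#' @param sep Field separator (default comma).
#' @return A named list of `conc_profile` objects (names `arm/matrix`).
#' @export
read_profiles <- function(source, analyte = NULL, sep = ",") {
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if ("time_min" %in% names(df) && !"time_h" %in% names(df)) {
    df$time_h <- df$time_min / 60
  }
  need <- c("arm", "matrix", "route", "dose_mg_per_kg", "time_h", "conc",
            "blq", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("input is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$time_h < 0)) {
    stop("negative time at row(s) ", paste(which(df$time_h < 0), collapse = ", "))
  }
  df$blq <- as.integer(df$blq) == 1L
  neg <- !df$blq & !is.na(df$conc) & df$conc < 0
  if (any(neg)) {
    stop("negative concentration at row(s) ", paste(which(neg), collapse = ", "))
  }
  key <- paste(df$arm, df$matrix, sep = "/")
  dup <- duplicated(cbind(key, df$time_h))
  if (any(dup)) {
    stop("duplicate (arm, matrix, time) at row(s) ",
         paste(which(dup), collapse = ", "))
  }
  if (!is.null(analyte) && length(analyte$lloq)) {
    lloq <- analyte$lloq[df$matrix]
    low <- !df$blq & !is.na(df$conc) & !is.na(lloq) & df$conc < lloq
    if (any(low)) {
      warning(sum(low), " record(s) below the matrix LLOQ were not flagged ",
              "BLQ; auto-flagging them")
      df$blq[low] <- TRUE
      df$conc[low] <- NA_real_
    }
  }
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), ]
    regimen <- dose_regimen(route = g$route[1],
                            dose_level = g$dose_mg_per_kg[1],
                            n_doses = if ("n_doses" %in% names(g))
                              g$n_doses[1] else 1L)
    conc_profile(arm_id = as.character(g$arm[1]),
                 matrix = as.character(g$matrix[1]), regimen = regimen,
                 data = data.frame(time = g$time_h, conc = g$conc,
                                   blq = g$blq, n = g$n),
                 analyte = analyte)
  })
  out[order(names(out))]
}

#' Write profiles back to the delimited dialect
#'
#' Inverse of [read_profiles()]: one row per (arm, matrix, time); BLQ records
#' are written with an empty concentration field and `blq = 1`.
#'
#' @param profiles List of [conc_profile()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(arm = p$arm_id, matrix = p$matrix, route = p$regimen$route,
               dose_mg_per_kg = p$regimen$dose_level, time_h = p$data$time,
               conc = p$data$conc, blq = as.integer(p$data$blq),
               n = p$data$n, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Censor below-limit-of-quantitation records
#'
#' Applies a deterministic BLQ rule before NCA. The default,
#' `"pre_tmax_zero_post_tmax_drop"`, is common NCA practice: BLQ samples in
#' the absorption phase (before the observed Tmax) are set to zero, BLQ
#' samples after Tmax are excluded so they cannot flatten the terminal slope.
#'
#' @param profile A [conc_profile()].
#' @param policy One of `"pre_tmax_zero_post_tmax_drop"`, `"drop_all"`,
#'   `"zero_all"`.
#' @return A `conc_profile` with no remaining BLQ flags. Idempotent.
#' @export
censor_blq <- function(profile,
                       policy = c("pre_tmax_zero_post_tmax_drop",
                                  "drop_all", "zero_all")) {
  stopifnot(inherits(profile, "conc_profile"))
  policy <- match.arg(policy)
  d <- profile$data
  if (all(d$blq)) stop("degenerate profile: all records are BLQ")
  if (!any(d$blq)) return(profile)
  keep <- rep(TRUE, nrow(d))
  if (policy == "drop_all") {
    keep <- !d$blq
  } else if (policy == "zero_all") {
    d$conc[d$blq] <- 0
  } else {
    tmax <- d$time[!d$blq][which.max(d$conc[!d$blq])]
    pre <- d$blq & d$time < tmax
    post <- d$blq & d$time >= tmax
    d$conc[pre] <- 0
    keep <- !post
  }
  d$blq <- FALSE
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("degenerate profile: empty after BLQ censoring")
  conc_profile(profile$arm_id, profile$matrix, profile$regimen, d,
               analyte = profile$analyte)
}
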