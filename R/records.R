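#' Subject records for the illness-death likelihood
#'
#' One row per individual with the observed-data tuple:
#' \describe{
#'   \item{id}{subject identifier.}
#'   \item{l1}{last examination time without the event of interest (0 if none);
#'     for subjects without an observed event this is the last known
#'     event-free time, for exactly observed events it equals `t1`.}
#'   \item{t1}{observation time of the event of interest: the exact event time
#'     (`exact = 1`), the first positive examination time (`exact = 0`), or
#'     the end of follow-up when no event was observed (`d1 = 0`).}
#'   \item{d1}{0/1 indicator of an observed event of interest.}
#'   \item{exact}{0/1: event time observed exactly vs interval censored
#'     (ignored when `d1 = 0`, conventionally 1 for a right-censored scheme).}
#'   \item{t2}{observation time of the competing event (death) or censoring.}
#'   \item{d2}{0/1 indicator of the (exactly observed) competing event.}
#' }
#' Additional columns (covariates) are carried through unchanged. The
#' interval convention is half-open: an interval-censored event lies in
#' `(l1, t1]`.
#'
#' @param df data frame with at least the columns above.
#' @return The validated data frame with class `"subject_records"` prepended.
#' @export
subject_records <- function(df) {
  df <- as.data.frame(df)
  req <- c("id", "l1", "t1", "d1", "exact", "t2", "d2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("empty dataset", call. = FALSE)
  # exact events may be written with l1 missing; it equals the event time
  fix <- is.na(df$l1) & df$d1 == 1 & df$exact == 1
  df$l1[fix] <- df$t1[fix]
  bad <- validate_records(df)
  if (length(bad))
    stop("invalid subject records:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  class(df) <- unique(c("subject_records", class(df)))
  df
}

#' @rdname subject_records
#' @return `validate_records()` returns a character vector of problems (empty
#'   when the data are valid), each naming the offending row.
#' @export
validate_records <- function(df) {
  msgs <- character()
  add <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      msgs <<- c(msgs, sprintf("row %d: %s", which(rows), what))
  }
  num <- c("l1", "t1", "t2")
  for (v in num) add(!is.finite(df[[v]]), paste0("non-finite ", v))
  ok <- Reduce(`&`, lapply(num, function(v) is.finite(df[[v]])))
  add(ok & !(df$d1 %in% 0:1), "d1 must be 0 or 1")
  add(ok & !(df$d2 %in% 0:1), "d2 must be 0 or 1")
  add(ok & !(df$exact %in% 0:1), "exact must be 0 or 1")
  add(ok & (df$l1 < 0), "l1 must be >= 0")
  add(ok & (df$t1 <= 0 | df$t2 <= 0), "observation times must be positive")
  add(ok & (df$l1 > df$t1), "l1 > t1")
  add(ok & (df$t1 > df$t2), "t1 > t2")
  e <- ok & df$d1 == 1 & df$exact == 1
  add(e & df$l1 != df$t1, "exact event requires l1 == t1")
  ic <- ok & df$d1 == 1 & df$exact == 0
  add(ic & df$l1 >= df$t1, "interval-censored event requires l1 < t1")
  no <- ok & df$d1 == 0
  add(no & df$t1 != df$t2, "no observed event requires t1 == t2 (end of follow-up)")
  msgs
}

#' Classify each record into one of the six likelihood trajectories
#'
#' The likelihood contribution takes one of three forms (exact event,
#' no observed event, interval-censored event), each split by the competing
#' event indicator. Codes 1-3 end in death (`d2 = 1`), codes 4-6 in
#' censoring, with pairs (1,4) exact, (2,5) no observed event, (3,6)
#' interval censored sharing a form.
#'
#' @param records a [subject_records()] data frame.
#' @return integer vector of trajectory codes in 1..6.
#' @export
classify_trajectory <- function(records) {
  records <- subject_records(records)
  base <- ifelse(records$d1 == 0, 2L, ifelse(records$exact == 1, 1L, 3L))
  base + 3L * (1L - as.integer(records$d2))
}

#' Read and write subject records as delimited text
#'
#' Files are comma separated with header
#' `id,l1,t1,d1,exact,t2,d2[,covariate...]`; times on the natural scale.
#' A missing `l1` for an exactly observed event is read as `l1 = t1`.
#'
#' @param path file path.
#' @param records a [subject_records()] data frame.
#' @export
read_subject_records <- function(path) {
  subject_records(read.csv(path))
}

#' @rdname read_subject_records
#' @export
write_subject_records <- function(records, path) {
  records <- subject_records(records)
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
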