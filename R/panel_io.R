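# Panel data model and the whitespace-delimited survey file format.
#
# Dates are carried at month resolution only, as absolute month indices
# year*12 + month, so ordering and interval lengths are plain integer
# arithmetic. An unknown death date is NA internally and the token "99/9999"
# on disk. A wave a subject did not attend at all is serialized as
# "99/9999 ." (no date, no state); an attended interview with unknown ADL
# state carries the real date and the missing-state sentinel 9.

UNKNOWN_DATE_TOKEN <- "99/9999"
NO_INTERVIEW_STATE <- "."
STATE_MISSING <- 9L

#' Absolute month index
#'
#' Maps a calendar month to the integer `year * 12 + month`, which is strictly
#' monotone in calendar time and makes interval lengths subtractions.
#'
#' @param month integer 1-12 (vectorized)
#' @param year calendar year (vectorized)
#' @return integer month index
#' @export
month_index <- function(month, year) {
  stopifnot(all(month >= 1 & month <= 12, na.rm = TRUE))
  as.integer(year) * 12L + as.integer(month)
}

#' Parse a mm/yyyy date token
#'
#' @param token character vector of `mm/yyyy` tokens; `"99/9999"` means
#'   unknown and maps to `NA`.
#' @return integer absolute month index, `NA` for the unknown token
#' @export
parse_month <- function(token) {
  token <- trimws(token)
  out <- rep(NA_integer_, length(token))
  known <- !is.na(token) & token != UNKNOWN_DATE_TOKEN
  if (any(known)) {
    parts <- regmatches(token[known],
                        regexec("^([0-9]{1,2})/([0-9]{4})$", token[known]))
    bad <- lengths(parts) != 3L
    if (any(bad)) {
      stop("unparsable date token(s): ",
           paste(unique(token[known][bad]), collapse = ", "),
           call. = FALSE)
    }
    mm <- as.integer(vapply(parts, `[`, "", 2L))
    yy <- as.integer(vapply(parts, `[`, "", 3L))
    if (any(mm < 1L | mm > 12L)) {
      stop("month outside 1-12 in date token(s): ",
           paste(token[known][mm < 1L | mm > 12L], collapse = ", "),
           call. = FALSE)
    }
    out[known] <- month_index(mm, yy)
  }
  out
}

#' Format an absolute month index as mm/yyyy
#'
#' @param idx integer month index; `NA` becomes the unknown token `"99/9999"`.
#' @return character vector
#' @export
format_month <- function(idx) {
  out <- rep(UNKNOWN_DATE_TOKEN, length(idx))
  known <- !is.na(idx)
  m <- ((as.integer(idx[known]) - 1L) %% 12L) + 1L
  y <- (as.integer(idx[known]) - m) %/% 12L
  out[known] <- sprintf("%02d/%04d", m, y)
  out
}

#' Construct a panel dataset
#'
#' The container for interval-censored panel data: one row per subject in
#' `subjects`, one row per attended interview in `obs` (long format, sorted by
#' subject then month).
#'
#' @param subjects data.frame with columns `id` (character, unique), `weight`
#'   (nonnegative; carried through, never used in fitting), `birth` and
#'   `death` (absolute month indices, `death` may be `NA`), `sex`, `hyp`,
#'   `diab` (each 0/1).
#' @param obs data.frame with columns `id`, `month` (absolute month index) and
#'   `state` (0 healthy, 1 disabled, 2 dead, 9 unknown).
#' @param wave_labels optional character labels, one per wave.
#' @param window death-ascertainment window end (absolute month index), or
#'   `NULL`. When present it asserts that every death up to that month is
#'   recorded (registry linkage), so an unknown death date means "alive at the
#'   window end"; the likelihood then credits survivors their survival.
#' @return object of class `panel_dataset`
#' @export
panel_dataset <- function(subjects, obs, wave_labels = NULL, window = NULL) {
  need_s <- c("id", "weight", "birth", "death", "sex", "hyp", "diab")
  need_o <- c("id", "month", "state")
  stopifnot(is.data.frame(subjects), all(need_s %in% names(subjects)),
            is.data.frame(obs), all(need_o %in% names(obs)))
  subjects$id <- as.character(subjects$id)
  obs$id <- as.character(obs$id)
  obs <- obs[order(match(obs$id, subjects$id), obs$month), , drop = FALSE]
  rownames(subjects) <- NULL
  rownames(obs) <- NULL
  if (!is.null(window)) window <- as.integer(window)
  structure(list(subjects = subjects, obs = obs,
                 wave_labels = wave_labels, window = window),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: %d subjects, %d interviews, %d known deaths%s\n",
              nrow(x$subjects), nrow(x$obs), sum(!is.na(x$subjects$death)),
              if (is.null(x$window)) "" else
                paste0(", deaths ascertained to ", format_month(x$window))))
  invisible(x)
}

#' Number of subjects in a panel dataset
#' @param dataset a `panel_dataset`
#' @return integer
#' @export
n_subjects <- function(dataset) nrow(dataset$subjects)

#' Extract one subject
#'
#' @param dataset a `panel_dataset`
#' @param id subject id
#' @return list with `id`, `weight`, `birth`, `death`, `profile`
#'   (named 0/1 vector sex/hyp/diab) and `observations`
#'   (data.frame month, state)
#' @export
get_subject <- function(dataset, id) {
  i <- match(as.character(id), dataset$subjects$id)
  if (is.na(i)) stop("no subject with id '", id, "'", call. = FALSE)
  s <- dataset$subjects[i, ]
  o <- dataset$obs[dataset$obs$id == s$id, c("month", "state")]
  rownames(o) <- NULL
  list(id = s$id, weight = s$weight, birth = s$birth, death = s$death,
       profile = c(sex = s$sex, hyp = s$hyp, diab = s$diab),
       observations = o, window = dataset$window)
}

# One validation finding.
finding <- function(id, rule, severity, message, line = NA_integer_) {
  data.frame(id = id, rule = rule, severity = severity,
             message = message, line = line, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(id = character(), rule = character(), severity = character(),
             message = character(), line = integer(),
             stringsAsFactors = FALSE)
}

#' Validate a panel dataset
#'
#' Checks the subject-level invariants and returns machine-readable findings
#' rather than raising: duplicated ids, nonmonotone interview dates,
#' observations before birth or after a recorded death, a known death not
#' strictly after the last interview month, negative weights, and subjects
#' with no usable (non-missing, live) observation.
#'
#' @param dataset a `panel_dataset`
#' @return data.frame of findings (`id`, `rule`, `severity`, `message`,
#'   `line`); zero rows iff every invariant holds.
#' @export
validate_dataset <- function(dataset) {
  out <- list(no_findings())
  sub <- dataset$subjects
  dup <- unique(sub$id[duplicated(sub$id)])
  for (d in dup) {
    out[[length(out) + 1L]] <-
      finding(d, "duplicate_id", "error", "subject id appears more than once")
  }
  if (any(sub$weight < 0, na.rm = TRUE)) {
    for (d in sub$id[!is.na(sub$weight) & sub$weight < 0]) {
      out[[length(out) + 1L]] <-
        finding(d, "negative_weight", "error", "survey weight is negative")
    }
  }
  obs_by_id <- split(dataset$obs, dataset$obs$id)
  for (i in seq_len(nrow(sub))) {
    id <- sub$id[i]
    o <- obs_by_id[[id]]
    if (is.null(o) || nrow(o) == 0L) {
      out[[length(out) + 1L]] <-
        finding(id, "no_usable_observation", "error",
                "subject has no interviews at all")
      next
    }
    if (is.unsorted(o$month, strictly = TRUE)) {
      out[[length(out) + 1L]] <-
        finding(id, "nonmonotone_dates", "error",
                "interview dates not strictly increasing")
    }
    if (any(o$month <= sub$birth[i])) {
      out[[length(out) + 1L]] <-
        finding(id, "obs_before_birth", "error",
                "interview at or before birth month")
    }
    if (!is.na(sub$death[i])) {
      # The death month is the elementary interval in which death occurs, so
      # it must lie strictly after the last interview month.
      if (any(o$month >= sub$death[i])) {
        out[[length(out) + 1L]] <-
          finding(id, "obs_after_death", "error",
                  sprintf("interview at %s not strictly before death %s",
                          format_month(max(o$month)),
                          format_month(sub$death[i])))
      }
    }
    if (!any(o$state %in% c(0L, 1L))) {
      out[[length(out) + 1L]] <-
        finding(id, "no_usable_observation", "warning",
                "no interview with a known live state (all missing/dead)")
    }
    if (any(!o$state %in% c(0L, 1L, 2L, 9L))) {
      out[[length(out) + 1L]] <-
        finding(id, "bad_state", "error", "state outside {0,1,2,9}")
    }
    # death is absorbing: nothing may follow a state-2 interview
    dead_at <- o$month[o$state == 2L]
    if (length(dead_at) && any(o$month > min(dead_at))) {
      out[[length(out) + 1L]] <-
        finding(id, "obs_after_death", "error",
                "interview recorded after a dead-state interview")
    }
  }
  do.call(rbind, out)
}

panel_header <- function(n_waves, window = NULL) {
  h <- sprintf("# waves=%d covariates=sex,hyp,diab", n_waves)
  if (!is.null(window)) h <- paste0(h, " window=", format_month(window))
  h
}

#' Read a panel survey file
#'
#' The format is self-describing: a header comment
#' `# waves=K covariates=sex,hyp,diab`, then one whitespace-separated row per
#' subject: `id weight birth death sex hyp diab` followed by K
#' `date state` pairs. Dates are `mm/yyyy` (`99/9999` = unknown/none); a wave
#' the subject did not attend is `99/9999 .`; state 9 marks an attended
#' interview with unknown ADL state.
#'
#' Structural problems (bad date token, state outside \{0,1,2,9\}) and
#' consistency violations (interview after recorded death, nonmonotone dates)
#' stop with the offending line number and subject id. Subjects with missing
#' or non-binary covariates are excluded with a logged finding, following the
#' convention that covariate-incomplete respondents drop out of the risk set.
#'
#' @param path file path
#' @return a `panel_dataset`; findings for excluded subjects are attached as
#'   `attr(, "findings")`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#\\s*waves=\\d+", lines[1])) {
    stop("missing '# waves=K covariates=...' header in ", path, call. = FALSE)
  }
  n_waves <- as.integer(sub("^#\\s*waves=(\\d+).*$", "\\1", lines[1]))
  window <- NULL
  if (grepl("window=", lines[1])) {
    window <- parse_month(sub("^.*window=(\\S+).*$", "\\1", lines[1]))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !grepl("^#", body)]
  n_fields <- 7L + 2L * n_waves

  subs <- vector("list", length(body))
  obss <- vector("list", length(body))
  findings <- list(no_findings())

  for (r in seq_along(body)) {
    ln <- r + 1L  # physical line number (header is line 1)
    f <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(f) != n_fields) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   ln, n_fields, length(f)), call. = FALSE)
    }
    id <- f[1]
    weight <- suppressWarnings(as.numeric(f[2]))
    if (is.na(weight)) {
      stop(sprintf("line %d (subject %s): unparsable weight '%s'",
                   ln, id, f[2]), call. = FALSE)
    }
    birth <- tryCatch(parse_month(f[3]), error = function(e) {
      stop(sprintf("line %d (subject %s): %s", ln, id, conditionMessage(e)),
           call. = FALSE)
    })
    if (is.na(birth)) {
      stop(sprintf("line %d (subject %s): birth date is required", ln, id),
           call. = FALSE)
    }
    death <- tryCatch(parse_month(f[4]), error = function(e) {
      stop(sprintf("line %d (subject %s): %s", ln, id, conditionMessage(e)),
           call. = FALSE)
    })
    cov <- suppressWarnings(as.integer(f[5:7]))
    if (any(is.na(cov)) || any(!cov %in% c(0L, 1L))) {
      findings[[length(findings) + 1L]] <-
        finding(id, "missing_covariate", "warning",
                "covariates not all in {0,1}; subject excluded at load", ln)
      next
    }
    months <- integer(0); states <- integer(0)
    for (w in seq_len(n_waves)) {
      dtok <- f[7L + 2L * w - 1L]
      stok <- f[7L + 2L * w]
      if (stok == NO_INTERVIEW_STATE) {
        if (dtok != UNKNOWN_DATE_TOKEN) {
          stop(sprintf(
            "line %d (subject %s): wave %d has a date but no state", ln, id, w),
            call. = FALSE)
        }
        next
      }
      st <- suppressWarnings(as.integer(stok))
      if (is.na(st) || !st %in% c(0L, 1L, 2L, 9L)) {
        stop(sprintf("line %d (subject %s): state '%s' outside {0,1,2,9}",
                     ln, id, stok), call. = FALSE)
      }
      m <- tryCatch(parse_month(dtok), error = function(e) {
        stop(sprintf("line %d (subject %s): %s", ln, id, conditionMessage(e)),
             call. = FALSE)
      })
      if (is.na(m)) {
        stop(sprintf("line %d (subject %s): wave %d has a state but no date",
                     ln, id, w), call. = FALSE)
      }
      months <- c(months, m); states <- c(states, st)
    }
    subs[[r]] <- data.frame(id = id, weight = weight, birth = birth,
                            death = death, sex = cov[1], hyp = cov[2],
                            diab = cov[3], stringsAsFactors = FALSE)
    if (length(months)) {
      obss[[r]] <- data.frame(id = id, month = months, state = states,
                              stringsAsFactors = FALSE)
    }
  }

  subjects <- do.call(rbind, subs[!vapply(subs, is.null, TRUE)])
  obs <- do.call(rbind, obss[!vapply(obss, is.null, TRUE)])
  if (is.null(subjects)) {
    subjects <- data.frame(id = character(), weight = numeric(),
                           birth = integer(), death = integer(),
                           sex = integer(), hyp = integer(), diab = integer(),
                           stringsAsFactors = FALSE)
  }
  if (is.null(obs)) {
    obs <- data.frame(id = character(), month = integer(), state = integer(),
                      stringsAsFactors = FALSE)
  }
  ds <- panel_dataset(subjects, obs,
                      wave_labels = paste0("wave", seq_len(n_waves)),
                      window = window)
  v <- validate_dataset(ds)
  errs <- v[v$severity == "error" & v$rule != "no_usable_observation", ]
  if (nrow(errs)) {
    stop("consistency error(s) in ", path, ": ",
         paste(sprintf("[%s] %s: %s", errs$id, errs$rule, errs$message),
               collapse = "; "), call. = FALSE)
  }
  fdf <- do.call(rbind, findings)
  attr(ds, "findings") <- rbind(fdf, v)
  ds
}

#' Write a panel dataset
#'
#' Emits exactly the layout [read_panel()] accepts, so write-then-read is the
#' identity on valid datasets. The number of wave columns is the maximum
#' interview count over subjects (minimum 1).
#'
#' @param dataset a `panel_dataset`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_panel <- function(dataset, path) {
  stopifnot(inherits(dataset, "panel_dataset"))
  counts <- table(factor(dataset$obs$id, levels = dataset$subjects$id))
  n_waves <- max(1L, if (length(counts)) max(counts) else 0L)
  lines <- panel_header(n_waves, dataset$window)
  if (nrow(dataset$subjects)) {
    obs_by_id <- split(dataset$obs, dataset$obs$id)
    rows <- vapply(seq_len(nrow(dataset$subjects)), function(i) {
      s <- dataset$subjects[i, ]
      o <- obs_by_id[[s$id]]
      waves <- character(0)
      if (!is.null(o) && nrow(o)) {
        waves <- paste(format_month(o$month), o$state)
      }
      pad <- n_waves - length(waves)
      if (pad > 0L) {
        waves <- c(waves,
                   rep(paste(UNKNOWN_DATE_TOKEN, NO_INTERVIEW_STATE), pad))
      }
      paste(s$id, format(s$weight, digits = 10), format_month(s$birth),
            format_month(s$death), s$sex, s$hyp, s$diab,
            paste(waves, collapse = " "))
    }, "")
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}
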