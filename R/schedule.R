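#' Transition-probability schedule
#'
#' Container for the (age, sex, calendar year)-indexed family of 10 x 10
#' row-stochastic transition matrices that drives the annual-cycle engine.
#' Ages run over a contiguous range (35-100 in the standard configuration);
#' the oldest age is open-ended: survivors at the cap reuse the cap-age
#' matrix in later cycles until death.
#'
#' @param p Numeric 5-dimensional array `[age, sex, year, from, to]`. The
#'   last two dimensions must have length 10 in canonical state order.
#' @param ages Contiguous integer vector of ages.
#' @param sexes Character vector, default `c("male", "female")`.
#' @param years Contiguous integer vector of calendar years.
#' @return An object of class `"transition_schedule"`: a list with elements
#'   `ages`, `sexes`, `years` and the probability array `p` (with dimnames).
#' @seealso [validate_schedule()], [read_schedule()], [write_schedule()]
#' @export
transition_schedule <- function(p, ages, sexes = c("male", "female"), years) {
  ages <- as.integer(ages); years <- as.integer(years)
  if (length(ages) > 1L && !all(diff(ages) == 1L)) {
    stop("ages must form a contiguous range")
  }
  if (length(years) > 1L && !all(diff(years) == 1L)) {
    stop("years must form a contiguous range")
  }
  expected <- c(length(ages), length(sexes), length(years), 10L, 10L)
  if (!is.numeric(p) || length(dim(p)) != 5L || !all(dim(p) == expected)) {
    stop("p must be a numeric array of dim [",
         paste(expected, collapse = " x "), "]")
  }
  dimnames(p) <- list(
    age = as.character(ages), sex = sexes, year = as.character(years),
    from = state_codes(), to = state_codes()
  )
  structure(list(ages = ages, sexes = sexes, years = years, p = p),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("<transition_schedule>\n",
      " ages:  ", min(x$ages), "-", max(x$ages), "\n",
      " sexes: ", paste(x$sexes, collapse = ", "), "\n",
      " years: ", min(x$years), "-", max(x$years), "\n",
      " matrices: ", length(x$ages) * length(x$sexes) * length(x$years),
      " (10 x 10)\n", sep = "")
  invisible(x)
}

#' Build a year-constant schedule from per-(age, sex) matrices
#'
#' @param mats List indexed `[[sex]][[age index]]` of 10 x 10 matrices, or a
#'   4-d array `[age, sex, from, to]`.
#' @inheritParams transition_schedule
#' @return A [transition_schedule()] with the same matrix replicated over
#'   `years`.
#' @export
constant_schedule <- function(mats, ages, sexes = c("male", "female"), years) {
  na <- length(ages); ns <- length(sexes); ny <- length(years)
  if (is.array(mats) && length(dim(mats)) == 4L) {
    base <- mats
  } else {
    base <- array(NA_real_, c(na, ns, 10L, 10L))
    for (s in seq_len(ns)) for (a in seq_len(na)) {
      base[a, s, , ] <- mats[[s]][[a]]
    }
  }
  p <- array(NA_real_, c(na, ns, ny, 10L, 10L))
  for (y in seq_len(ny)) p[, , y, , ] <- base
  transition_schedule(p, ages, sexes, years)
}

#' Validate a transition schedule
#'
#' Checks every (age, sex, year, from-state) row of the schedule against the
#' container's invariants and, optionally, a transition mask:
#'
#' * all entries in \[0, 1\] and non-missing;
#' * every row sums to 1 within `tol`;
#' * death-state rows are identity rows (death is absorbing);
#' * arcs forbidden by `mask` carry probability exactly 0.
#'
#' Nothing is repaired: violations are reported with their coordinates.
#'
#' @param schedule A [transition_schedule()].
#' @param mask Optional [transition_mask()].
#' @param tol Row-sum tolerance (default `1e-9`).
#' @return A data frame with columns `age`, `sex`, `year`, `from_state`,
#'   `issue`, `detail`; zero rows iff the schedule is valid. Class
#'   `"validation_report"`.
#' @export
validate_schedule <- function(schedule, mask = NULL, tol = 1e-9) {
  stopifnot(inherits(schedule, "transition_schedule"))
  p <- schedule$p
  dn <- dim(p)[1:4]
  codes <- state_codes()
  grid_names <- list(age = schedule$ages,
                     sex = schedule$sexes,
                     year = schedule$years,
                     from_state = codes)
  rows <- list()
  add <- function(idx, issue, detail) {
    # idx: integer matrix with columns (age, sex, year, from)
    rows[[length(rows) + 1L]] <<- data.frame(
      age = grid_names$age[idx[, 1L]],
      sex = grid_names$sex[idx[, 2L]],
      year = grid_names$year[idx[, 3L]],
      from_state = grid_names$from_state[idx[, 4L]],
      issue = issue,
      detail = detail,
      stringsAsFactors = FALSE
    )
  }
  row_idx <- function(flags) {
    # flags: logical array over [age, sex, year, from]
    which(flags, arr.ind = TRUE)
  }

  pm <- matrix(p, ncol = 10L)  # rows indexed by (age, sex, year, from)

  miss <- array(rowSums(is.na(pm)) > 0L, dn)
  if (any(miss)) add(row_idx(miss), "missing", "row contains missing probabilities")

  oor <- array(rowSums(!is.na(pm) & (pm < 0 | pm > 1)) > 0L, dn)
  if (any(oor)) add(row_idx(oor), "out_of_range", "probability outside [0, 1]")

  rs <- array(rowSums(pm), dn)
  bad_sum <- !is.na(rs) & abs(rs - 1) > tol
  if (any(bad_sum)) {
    idx <- row_idx(bad_sum)
    add(idx, "row_sum", sprintf("row sums to %.12g", rs[bad_sum]))
  }

  # death rows must be identity
  for (d in death_states()) {
    di <- .state_index(d)
    block <- p[, , , di, , drop = FALSE]
    ident <- rep(0, 10L); ident[di] <- 1
    dev <- sweep(block, 5L, ident, "-")
    bad <- array(rowSums(abs(matrix(dev, ncol = 10L))) > tol, dn[1:3])
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)
      idx <- cbind(idx, from = di)
      add(idx, "death_not_absorbing",
          paste0("row for ", d, " is not an identity row"))
    }
  }

  if (!is.null(mask)) {
    forb <- !mask  # [from, to]
    viol <- array(FALSE, dn)
    labels <- array("", dn)
    for (i in 1:10) {
      fj <- which(forb[i, ])
      if (length(fj) == 0L) next
      block <- p[, , , i, fj, drop = FALSE]
      bad <- array(rowSums(matrix(block != 0, ncol = length(fj))) > 0L, dn[1:3])
      if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)
        # name the offending arcs for each violating row
        det <- apply(idx, 1L, function(k) {
          vals <- p[k[1L], k[2L], k[3L], i, fj]
          arcs <- codes[fj][vals != 0]
          paste0("masked arc(s) nonzero: ",
                 paste(codes[i], "->", arcs, collapse = "; "))
        })
        add(cbind(idx, from = i), "masked_arc_nonzero", det)
      }
    }
  }

  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
    age = integer(), sex = character(), year = integer(),
    from_state = character(), issue = character(), detail = character(),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$year, out$sex, out$age, match(out$from_state, codes)), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation_report> no violations\n")
  } else {
    cat("<validation_report>", nrow(x), "violation(s)\n")
    print.data.frame(x, ...)
  }
  invisible(x)
}

# number of decimal significant digits preserved by the long-table format
.SCHEDULE_SIGDIGITS <- 12L

.open_read <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read a transition schedule from a delimited long table
#'
#' The file must be UTF-8 delimited text (comma by default, tab detected
#' automatically) with a header row and columns `age`, `sex`, `year`,
#' `from_state`, `to_state`, `probability`. Gzip-compressed files are
#' accepted by `.gz` extension.
#'
#' With `complete = TRUE` (the default) every (from, to) pair must be
#' present for every (age, sex, year) row. With `complete = FALSE`,
#' unspecified pairs default to 0, except the self-transition of each row,
#' which — when not given explicitly — absorbs the remainder needed to make
#' the row stochastic.
#'
#' @param path File path.
#' @param complete Logical dialect flag, see Details.
#' @return A [transition_schedule()].
#' @export
read_schedule <- function(path, complete = TRUE) {
  con <- .open_read(path)
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- strsplit(first, sep, fixed = TRUE)[[1]]
  required <- c("age", "sex", "year", "from_state", "to_state", "probability")
  if (!all(required %in% header)) {
    stop("schedule file must have header columns: ",
         paste(required, collapse = ", "))
  }
  df <- utils::read.table(con, sep = sep, header = FALSE,
                          col.names = header, stringsAsFactors = FALSE,
                          colClasses = NA, encoding = "UTF-8")
  df <- df[required]
  n <- nrow(df)
  if (n == 0L) stop("schedule file contains no data rows")

  codes <- state_codes()
  bad_state <- !(df$from_state %in% codes) | !(df$to_state %in% codes)
  if (any(bad_state)) {
    stop("unknown state code(s) at data row(s) ",
         paste(utils::head(which(bad_state), 5L), collapse = ", "),
         ": ", paste(unique(c(df$from_state[bad_state],
                              df$to_state[bad_state])), collapse = ", "))
  }
  bad_p <- is.na(df$probability) | df$probability < 0 | df$probability > 1
  if (any(bad_p)) {
    stop("probability outside [0, 1] at data row(s): ",
         paste(utils::head(which(bad_p), 10L), collapse = ", "))
  }

  key <- paste(df$age, df$sex, df$year, df$from_state, df$to_state)
  if (anyDuplicated(key)) {
    stop("duplicate (age, sex, year, from, to) rows, e.g. data row(s): ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  }

  ages <- sort(unique(df$age))
  years <- sort(unique(df$year))
  sexes <- intersect(c("male", "female"), unique(df$sex))
  if (length(sexes) == 0L) sexes <- sort(unique(df$sex))

  p <- array(0, c(length(ages), length(sexes), length(years), 10L, 10L))
  ai <- match(df$age, ages)
  si <- match(df$sex, sexes)
  yi <- match(df$year, years)
  fi <- match(df$from_state, codes)
  ti <- match(df$to_state, codes)
  p[cbind(ai, si, yi, fi, ti)] <- df$probability

  specified <- array(FALSE, dim(p))
  specified[cbind(ai, si, yi, fi, ti)] <- TRUE
  spec_rows <- array(rowSums(matrix(specified, ncol = 10L)) > 0L,
                     dim(p)[1:4])

  if (complete) {
    n_missing <- sum(!specified[spec_rows])
    full <- length(ages) * length(sexes) * length(years) * 10L
    if (sum(spec_rows) < full || n_missing > 0L) {
      stop("complete = TRUE but the file does not enumerate every ",
           "(age, sex, year, from, to) combination (",
           sum(!specified), " missing entries over the index grid)")
    }
  } else {
    # self-transitions absorb the remainder where not explicitly given
    for (f in 1:10) {
      self_given <- specified[, , , f, f]
      others <- p[, , , f, , drop = FALSE]
      others[, , , 1L, f] <- 0
      resid <- 1 - array(rowSums(matrix(others, ncol = 10L)), dim(p)[1:3])
      if (any(!self_given & resid < -1e-12)) {
        stop("non-self probabilities for from-state ", codes[f],
             " exceed 1; self-transition remainder would be negative")
      }
      fill <- !self_given
      cur <- p[, , , f, f]
      cur[fill] <- pmax(resid[fill], 0)
      p[, , , f, f] <- cur
    }
  }

  transition_schedule(p, ages, sexes, years)
}

#' Write a transition schedule as a delimited long table
#'
#' The output enumerates every arc, sorted by (year, sex, age, from, to) in
#' canonical state order, with probabilities printed to 12 significant
#' digits. Output bytes are deterministic for a given schedule, and a write
#' / read cycle reproduces the schedule to the printed precision.
#'
#' @param schedule A [transition_schedule()].
#' @param path Output path; `.gz` extension writes gzip.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, sep = ",") {
  stopifnot(inherits(schedule, "transition_schedule"))
  codes <- state_codes()
  grid <- expand.grid(
    to_state = codes, from_state = codes,
    age = schedule$ages, sex = schedule$sexes, year = schedule$years,
    stringsAsFactors = FALSE
  )
  # array extraction in matching order: vary to fastest, then from, age, sex, year
  pv <- aperm(schedule$p, c(5L, 4L, 1L, 2L, 3L))
  lines <- paste(grid$age, grid$sex, grid$year, grid$from_state,
                 grid$to_state,
                 sprintf("%.*g", .SCHEDULE_SIGDIGITS, as.vector(pv)),
                 sep = sep)
  con <- .open_write(path)
  on.exit(close(con))
  writeLines(c(paste(c("age", "sex", "year", "from_state", "to_state",
                       "probability"), collapse = sep), lines), con)
  invisible(path)
}
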