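#' Count response data
#'
#' Container for long-format person-by-item count observations, the input
#' to every model-fitting and diagnostic function in the package. Missing
#' responses are represented by the absence of a record; there are no
#' sentinel values, and all downstream sums run over observed pairs only.
#'
#' @param person character vector of person identifiers.
#' @param item character vector of item identifiers, same length.
#' @param count non-negative integer scores, same length.
#'
#' @details Person and item ids are opaque strings ordered by first
#'   appearance. Invariants enforced: counts are integers >= 0, at most one
#'   record per (person, item) pair, and every person and item has at least
#'   one record (guaranteed by construction).
#'
#' @return An object of class `count_data`: a list with elements
#'   `records` (data.frame with columns person, item, count),
#'   `persons` and `items` (ordered unique id vectors).
#' @export
#' @examples
#' d <- count_data(c("P1", "P1", "P2"), c("I1", "I2", "I1"), c(5L, 3L, 0L))
#' d$persons
count_data <- function(person, item, count) {
  person <- as.character(person)
  item <- as.character(item)
  if (length(person) != length(item) || length(person) != length(count)) {
    stop("person, item and count must have equal length")
  }
  if (anyNA(person) || anyNA(item) || anyNA(count)) {
    stop("missing values are not allowed in count_data records")
  }
  if (any(count < 0)) {
    stop("negative score found: counts must be non-negative integers")
  }
  if (any(abs(count - round(count)) > 1e-8)) {
    bad <- which(abs(count - round(count)) > 1e-8)[1L]
    stop(sprintf("non-integer score %s at record %d (person %s, item %s)",
                 format(count[bad]), bad, person[bad], item[bad]))
  }
  count <- as.integer(round(count))
  key <- paste(person, item, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("duplicate record for (person, item) pair: %s",
                 gsub("\r", ", ", dup, fixed = TRUE)))
  }
  structure(list(
    records = data.frame(person = person, item = item, count = count,
                         stringsAsFactors = FALSE),
    persons = unique(person),
    items = unique(item)
  ), class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf("count_data: %d records, %d persons, %d items\n",
              nrow(x$records), length(x$persons), length(x$items)))
  cat(sprintf("  score range: %d..%d\n",
              min(x$records$count), max(x$records$count)))
  invisible(x)
}

# 0-based-free integer indices into persons/items for fast arithmetic
person_idx <- function(data) match(data$records$person, data$persons)
item_idx <- function(data) match(data$records$item, data$items)

#' Read long-format count data from CSV
#'
#' Expects one observation per row. Rows with a missing score are dropped
#' (with a message reporting how many); negative or fractional scores are
#' an error naming the offending row.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param person_col,item_col,score_col column names (defaults `Person`,
#'   `Item`, `Score`).
#' @return A [count_data] object.
#' @export
read_long <- function(path, person_col = "Person", item_col = "Item",
                      score_col = "Score") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c(person_col, item_col, score_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not present in %s", col, path))
    }
  }
  score <- df[[score_col]]
  drop <- is.na(score) | (is.character(score) & !nzchar(trimws(score)))
  if (any(drop)) {
    message(sprintf("read_long: dropped %d row(s) with missing score",
                    sum(drop)))
    df <- df[!drop, , drop = FALSE]
    score <- df[[score_col]]
  }
  score_num <- suppressWarnings(as.numeric(score))
  if (anyNA(score_num)) {
    bad <- which(is.na(score_num))[1L]
    stop(sprintf("non-numeric score '%s' in row %d", score[bad], bad))
  }
  if (any(abs(score_num - round(score_num)) > 1e-8)) {
    bad <- which(abs(score_num - round(score_num)) > 1e-8)[1L]
    stop(sprintf("non-integer score %s in row %d", format(score_num[bad]),
                 bad))
  }
  if (any(score_num < 0)) {
    bad <- which(score_num < 0)[1L]
    stop(sprintf("negative score %s in row %d", format(score_num[bad]), bad))
  }
  count_data(df[[person_col]], df[[item_col]], score_num)
}

#' Read wide-format count data from CSV
#'
#' One row per person, one column per item; empty cells become missing
#' observations (no record). Duplicate person ids are an error.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param person_col name of the person-id column (default `Person`).
#' @return A [count_data] object.
#' @export
read_wide <- function(path, person_col = "Person") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  if (!person_col %in% names(df)) {
    stop(sprintf("column '%s' not present in %s", person_col, path))
  }
  persons <- as.character(df[[person_col]])
  if (anyDuplicated(persons)) {
    stop(sprintf("duplicate person id '%s' in wide table",
                 persons[duplicated(persons)][1L]))
  }
  item_cols <- setdiff(names(df), person_col)
  if (!length(item_cols)) stop("wide table has no item columns")
  p <- character(0); it <- character(0); ct <- numeric(0)
  for (col in item_cols) {
    v <- df[[col]]
    keep <- !(is.na(v) | (is.character(v) & !nzchar(trimws(v))))
    p <- c(p, persons[keep])
    it <- c(it, rep(col, sum(keep)))
    ct <- c(ct, as.numeric(v[keep]))
  }
  # restore person-major first-appearance order to match read_long of the
  # pivoted table
  ord <- order(match(p, persons), match(it, item_cols))
  count_data(p[ord], it[ord], ct[ord])
}

#' Write count data as long-format CSV
#'
#' Mirrors the [read_long] dialect so that `read_long(write_long(d))` is
#' the identity.
#'
#' @param data a [count_data] object.
#' @param path output path.
#' @param person_col,item_col,score_col column names to use.
#' @return `path`, invisibly.
#' @export
write_long <- function(data, path, person_col = "Person",
                       item_col = "Item", score_col = "Score") {
  stopifnot(inherits(data, "count_data"))
  out <- data$records
  names(out) <- c(person_col, item_col, score_col)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write count data as wide-format CSV
#'
#' One row per person, one column per item; unobserved cells are left
#' empty.
#'
#' @inheritParams write_long
#' @export
write_wide <- function(data, path, person_col = "Person") {
  stopifnot(inherits(data, "count_data"))
  wide <- matrix(NA_integer_, nrow = length(data$persons),
                 ncol = length(data$items),
                 dimnames = list(NULL, data$items))
  wide[cbind(person_idx(data), item_idx(data))] <- data$records$count
  out <- data.frame(data$persons, wide, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1L] <- person_col
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Simulation configuration
#'
#' Describes a synthetic dataset: latent abilities theta_i drawn from
#' Normal(0, theta_sd^2) and counts drawn from Poisson(exp(b_j + a_j *
#' theta_i)) for each observed (person, item) pair. Defaults emulate the
#' shape of a 202-person, 3-item alternate-uses fluency test in which one
#' person answered a single item.
#'
#' @param n_persons number of persons.
#' @param item_params an [item_params] object giving easiness/slopes.
#' @param theta_sd latent standard deviation (> 0, default 1).
#' @param missing_pattern optional two-column matrix or data.frame of
#'   (person index, item index) pairs (1-based) to drop. May not remove
#'   all of a person's records.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_persons, item_params, theta_sd = 1,
                       missing_pattern = NULL, seed = 1L) {
  stopifnot(inherits(item_params, "item_params"))
  if (!is.numeric(n_persons) || n_persons < 1) stop("n_persons must be >= 1")
  if (!is.numeric(theta_sd) || theta_sd <= 0) stop("theta_sd must be > 0")
  m <- length(item_params$item_ids)
  if (!is.null(missing_pattern)) {
    missing_pattern <- as.matrix(missing_pattern)
    if (ncol(missing_pattern) != 2L) {
      stop("missing_pattern must have two columns (person, item index)")
    }
    if (any(missing_pattern[, 1L] < 1 | missing_pattern[, 1L] > n_persons) ||
        any(missing_pattern[, 2L] < 1 | missing_pattern[, 2L] > m)) {
      stop("missing_pattern indices out of range")
    }
    dropped_per_person <- table(factor(missing_pattern[, 1L],
                                       levels = seq_len(n_persons)))
    if (any(dropped_per_person >= m)) {
      stop("missing_pattern would remove all records of at least one person")
    }
  }
  structure(list(n_persons = as.integer(n_persons),
                 item_params = item_params, theta_sd = theta_sd,
                 missing_pattern = missing_pattern,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a count-response dataset
#'
#' Forward simulation from the 2PPCM (the RPCM being the equal-slope
#' special case): theta_i ~ N(0, theta_sd^2), X_ij ~ Poisson(exp(b_j +
#' a_j theta_i)). Used as the synthetic-data backbone of the test suite.
#'
#' @param config a [sim_config] object.
#' @return A list with elements `data` (a [count_data]) and `theta`
#'   (named numeric vector of true abilities, one per person).
#' @export
#' @examples
#' ip <- item_params(paste0("I", 1:3), easiness = c(2.0, 1.7, 2.1),
#'                   slope = c(0.3, 0.35, 0.4), model_kind = "2PPCM")
#' sim <- simulate_dataset(sim_config(50, ip, seed = 42))
#' sim$data
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ip <- config$item_params
  n <- config$n_persons
  m <- length(ip$item_ids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  theta <- stats::rnorm(n, 0, config$theta_sd)
  person_ids <- sprintf("P%d", seq_len(n))
  names(theta) <- person_ids
  # person-major grid of all (i, j) pairs
  pi_ <- rep(seq_len(n), each = m)
  ii <- rep(seq_len(m), times = n)
  keep <- rep(TRUE, n * m)
  if (!is.null(config$missing_pattern)) {
    drop_key <- (config$missing_pattern[, 1L] - 1L) * m +
      config$missing_pattern[, 2L]
    keep[drop_key] <- FALSE
  }
  lambda <- exp(ip$easiness[ii] + ip$slope[ii] * theta[pi_])
  counts <- stats::rpois(n * m, lambda)
  dat <- count_data(person_ids[pi_[keep]], ip$item_ids[ii[keep]],
                    counts[keep])
  list(data = dat, theta = theta)
}

# save/restore global RNG state so simulation seeds don't clobber callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
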