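#' Read germination trials from CSV
#'
#' Long format, one row per trial day on which at least one seed germinated:
#' columns `species_id, condition, storage, replicate, n_sown, day, count`.
#' Days absent from the file are implicitly zero; a trial in which nothing
#' germinated is represented by a single row with `day` and `count` empty or
#' zero.
#'
#' @param path CSV file path.
#' @param config a [germ_config()]; supplies the trial duration.
#' @return object of class `germ_trials`: list with `trials` (one row per
#'   replicate dish: `trial_id, species_id, condition, storage, replicate,
#'   n_sown`) and `counts` (one row per germination day:
#'   `trial_id, day, count`).
#' @export
read_trials <- function(path, config = germ_config()) {
  if (!file.exists(path)) stop("trials file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "condition", "storage", "replicate",
            "n_sown", "day", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trials file lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(new_germ_trials(empty = TRUE))

  rowno <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_cond <- !(df$condition %in% GERM_CONDITIONS)
  if (any(bad_cond))
    stop(sprintf("row %d: unknown condition label '%s'",
                 rowno[bad_cond][1], df$condition[bad_cond][1]))
  bad_sto <- !(df$storage %in% STORAGES)
  if (any(bad_sto))
    stop(sprintf("row %d: unknown storage label '%s'",
                 rowno[bad_sto][1], df$storage[bad_sto][1]))
  num_bad <- function(x) !is.finite(x) | x != round(x)
  if (any(num_bad(df$n_sown) | df$n_sown <= 0))
    stop(sprintf("row %d: n_sown must be a positive integer",
                 rowno[num_bad(df$n_sown) | df$n_sown <= 0][1]))
  if (any(num_bad(df$replicate) | df$replicate < 1))
    stop(sprintf("row %d: replicate must be an integer >= 1",
                 rowno[num_bad(df$replicate) | df$replicate < 1][1]))
  # zero-germination marker rows: day and count both empty/zero
  marker <- (is.na(df$day) | df$day == 0) & (is.na(df$count) | df$count == 0)
  chk <- !marker
  bad_day <- chk & (num_bad(df$day) | df$day < 1 |
                      df$day > config$trial_duration_days)
  if (any(bad_day))
    stop(sprintf("row %d: day must lie in 1..%d",
                 rowno[bad_day][1], config$trial_duration_days))
  bad_cnt <- chk & (num_bad(df$count) | df$count < 0)
  if (any(bad_cnt))
    stop(sprintf("row %d: count must be a non-negative integer",
                 rowno[bad_cnt][1]))

  key <- paste(df$species_id, df$condition, df$storage, df$replicate,
               sep = "\r")
  dup <- duplicated(data.frame(key, day = df$day)) & chk
  if (any(dup))
    stop(sprintf("row %d: duplicate day within trial", rowno[dup][1]))

  first <- !duplicated(key)
  trials <- data.frame(
    trial_id = seq_len(sum(first)),
    species_id = as.character(df$species_id[first]),
    condition = df$condition[first],
    storage = df$storage[first],
    replicate = as.integer(df$replicate[first]),
    n_sown = as.integer(df$n_sown[first]),
    stringsAsFactors = FALSE
  )
  tid <- match(key, key[first])
  if (any(df$n_sown != trials$n_sown[tid]))
    stop("inconsistent n_sown within trial ",
         trial_label(trials[tid[which(df$n_sown != trials$n_sown[tid])[1]], ]))
  keep <- chk & df$count > 0
  counts <- data.frame(trial_id = tid[keep],
                       day = as.integer(df$day[keep]),
                       count = as.integer(df$count[keep]))
  x <- new_germ_trials(trials = trials, counts = counts)
  validate_germ_trials(x)
  x
}

new_germ_trials <- function(trials = NULL, counts = NULL, empty = FALSE) {
  if (empty) {
    trials <- data.frame(trial_id = integer(), species_id = character(),
                         condition = character(), storage = character(),
                         replicate = integer(), n_sown = integer(),
                         stringsAsFactors = FALSE)
    counts <- data.frame(trial_id = integer(), day = integer(),
                         count = integer())
  }
  structure(list(trials = trials, counts = counts), class = "germ_trials")
}

trial_label <- function(row) {
  sprintf("%s/%s/%s/rep%d", row$species_id, row$condition, row$storage,
          row$replicate)
}

validate_germ_trials <- function(x) {
  tot <- germinated_totals(x)
  over <- tot > x$trials$n_sown
  if (any(over))
    stop("germinated seeds exceed n_sown in trial ",
         trial_label(x$trials[which(over)[1], ]))
  invisible(x)
}

# Per-trial totals: final germinated count and the day-weighted sum
# sum_i G_i / i that the germination-rate index needs.
germinated_totals <- function(x) {
  tot <- numeric(nrow(x$trials))
  if (nrow(x$counts) > 0) {
    agg <- rowsum(x$counts$count, x$counts$trial_id)
    tot[match(as.integer(rownames(agg)), x$trials$trial_id)] <- agg[, 1]
  }
  tot
}

day_weighted_totals <- function(x) {
  tot <- numeric(nrow(x$trials))
  if (nrow(x$counts) > 0) {
    agg <- rowsum(x$counts$count / x$counts$day, x$counts$trial_id)
    tot[match(as.integer(rownames(agg)), x$trials$trial_id)] <- agg[, 1]
  }
  tot
}

#' @export
print.germ_trials <- function(x, ...) {
  cat(sprintf(
    "germination trials: %d dishes, %d species, %d condition x storage cells\n",
    nrow(x$trials), length(unique(x$trials$species_id)),
    nrow(unique(x$trials[, c("condition", "storage")]))))
  invisible(x)
}

# Subset a germ_trials object by trial-level predicate (logical over trials).
filter_trials <- function(x, keep) {
  ids <- x$trials$trial_id[keep]
  new_germ_trials(trials = x$trials[keep, , drop = FALSE],
                  counts = x$counts[x$counts$trial_id %in% ids, , drop = FALSE])
}

#' Read vegetation quadrats from CSV
#'
#' Columns `block, n_level, species_id, count`; one row per species per
#' quadrat, one quadrat per block x nitrogen level.
#'
#' @param path CSV file path.
#' @return data.frame of class `quadrats` with columns
#'   `block_id, n_level, species_id, count`.
#' @export
read_quadrats <- function(path) {
  if (!file.exists(path)) stop("quadrats file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "n_level", "species_id", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("quadrats file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !(df$n_level %in% N_LEVELS)
  if (any(bad))
    stop(sprintf("unknown n_level label '%s' (row %d)",
                 df$n_level[bad][1], which(bad)[1] + 1L))
  if (any(!is.finite(df$count) | df$count < 0 | df$count != round(df$count)))
    stop("count must be a non-negative integer")
  dup <- duplicated(df[, c("block", "n_level", "species_id")])
  if (any(dup))
    stop(sprintf("duplicate (block, n_level, species) row: (%s, %s, %s)",
                 df$block[dup][1], df$n_level[dup][1], df$species_id[dup][1]))
  out <- data.frame(block_id = as.character(df$block),
                    n_level = df$n_level,
                    species_id = as.character(df$species_id),
                    count = as.integer(df$count),
                    stringsAsFactors = FALSE)
  tot <- rowsum(out$count, paste(out$block_id, out$n_level))
  if (any(tot[, 1] == 0))
    stop("quadrat with no individuals: ", rownames(tot)[tot[, 1] == 0][1])
  class(out) <- c("quadrats", "data.frame")
  out
}

#' Write a result table to CSV
#'
#' Writes any homogeneous record table with a stable column order; floating
#' point values are rendered at 10 significant digits so the file
#' round-trips, and undefined values become empty cells.
#'
#' @param records a data.frame.
#' @param path destination path (directory must exist).
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write ", path, ": directory does not exist")
  out <- as.data.frame(records, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- ifelse(is.na(v), NA_character_,
                  ifelse(v == round(v) & abs(v) < 1e15,
                         sprintf("%.0f", v),
                         formatC(v, digits = 10, format = "g")))
      out[[j]] <- s
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
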