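#' SDQ item metadata
#'
#' The 25 self-report SDQ items, five per subscale.  Problem items that are
#' positively worded (\code{obeys}, \code{reflective}, \code{attends},
#' \code{friend}, \code{popular}) are reverse-scored before scale scoring and
#' modeling so that a higher latent value always means more problems; the five
#' prosocial items are positively worded but keep their direction (higher =
#' more prosocial).
#'
#' @return data.frame with columns \code{item_id}, \code{scale},
#'   \code{positively_worded}, \code{reverse_scored}.
#' @export
sdq_item_meta <- function() {
  items <- c(
    "somatic", "worries", "unhappy", "clingy", "afraid",
    "tantrum", "obeys", "fights", "lies", "steals",
    "restless", "fidgety", "distractible", "reflective", "attends",
    "loner", "friend", "popular", "bullied", "oldbest",
    "considerate", "shares", "caring", "kind", "helpout"
  )
  scales <- rep(c("emotion", "conduct", "hyper", "peer", "prosocial"), each = 5L)
  pos <- items %in% c("obeys", "reflective", "attends", "friend", "popular",
                      "considerate", "shares", "caring", "kind", "helpout")
  rev <- items %in% c("obeys", "reflective", "attends", "friend", "popular")
  data.frame(item_id = items, scale = scales,
             positively_worded = pos, reverse_scored = rev,
             stringsAsFactors = FALSE)
}

sdq_scales <- function() c("emotion", "conduct", "hyper", "peer", "prosocial")

.assert_items <- function(items) {
  meta <- sdq_item_meta()
  bad <- setdiff(items, meta$item_id)
  if (length(bad))
    stop("unknown SDQ item column(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Construct an item-response matrix object
#'
#' @param responses integer matrix (persons x 25) with values in {0,1,2} or NA,
#'   columns named by SDQ item ids.
#' @param group factor or character vector (two levels) of person group labels.
#' @return object of class \code{sdq_matrix}: list with \code{responses}
#'   (integer matrix), \code{group} (factor), \code{n_per_group}.
#' @export
sdq_matrix <- function(responses, group) {
  responses <- as.matrix(responses)
  meta <- sdq_item_meta()
  if (is.null(colnames(responses)))
    stop("response matrix must have item-id column names")
  .assert_items(colnames(responses))
  if (!setequal(colnames(responses), meta$item_id))
    stop("expected all 25 SDQ items; missing: ",
         paste(setdiff(meta$item_id, colnames(responses)), collapse = ", "))
  responses <- responses[, meta$item_id, drop = FALSE]
  bad <- which(!is.na(responses) & !(responses %in% 0:2), arr.ind = TRUE)
  if (nrow(bad))
    stop("response values outside {0,1,2,NA}; first offending row: ", bad[1, 1])
  storage.mode(responses) <- "integer"
  ## level order = order of first appearance; the first level is treated as
  ## the reference group by the multigroup machinery
  group <- factor(as.character(group), levels = unique(as.character(group)))
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels, got ", nlevels(group))
  if (length(group) != nrow(responses))
    stop("group length does not match number of persons")
  structure(list(responses = responses, group = group,
                 n_per_group = table(group)),
            class = "sdq_matrix")
}

#' @export
print.sdq_matrix <- function(x, ...) {
  cat("SDQ item-response matrix:", nrow(x$responses), "persons x",
      ncol(x$responses), "items\n")
  print(x$n_per_group)
  miss <- mean(is.na(x$responses))
  cat(sprintf("missing cells: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Read item responses from a CSV file
#'
#' Expects one row per person, a \code{group} column, and one column per SDQ
#' item (header row of item ids).  Missing values may be empty cells or
#' \code{NA}.
#'
#' @param path path to a comma-separated file.
#' @return \code{\link{sdq_matrix}} object.
#' @export
load_item_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"group" %in% names(df)) stop("input file must contain a 'group' column")
  items <- setdiff(names(df), "group")
  .assert_items(items)
  resp <- as.matrix(df[, items, drop = FALSE])
  bad_val <- which(!is.na(resp) & !(resp %in% 0:2), arr.ind = TRUE)
  if (nrow(bad_val))
    stop("value outside {0,1,2,NA} at data row ", bad_val[1, 1],
         ", item '", items[bad_val[1, 2]], "'")
  sdq_matrix(resp, df$group)
}

#' Write item responses to a CSV file
#'
#' @param m an \code{sdq_matrix}.
#' @param path output path.
#' @export
write_item_responses <- function(m, path) {
  df <- data.frame(group = as.character(m$group), m$responses,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

## apply reversal x -> 2 - x to the reverse-scored items
reverse_items <- function(responses, meta = sdq_item_meta()) {
  rev <- meta$item_id[meta$reverse_scored]
  responses[, rev] <- 2L - responses[, rev]
  responses
}

#' Score SDQ subscales and total difficulties
#'
#' Reversal (x -> 2 - x) is applied internally to the five reverse-scored
#' problem items; raw responses are expected.  A person with any missing item
#' within a subscale receives a missing subscale score.  Total difficulties is
#' the sum of the four problem subscales (prosocial excluded).
#'
#' @param m an \code{sdq_matrix}.
#' @return data.frame with one row per person: the five subscale scores (0-10)
#'   and \code{total} (0-40).
#' @export
score_sdq <- function(m) {
  meta <- sdq_item_meta()
  resp <- reverse_items(m$responses, meta)
  out <- lapply(sdq_scales(), function(sc) {
    cols <- meta$item_id[meta$scale == sc]
    rowSums(resp[, cols, drop = FALSE])    # NA if any item missing
  })
  names(out) <- sdq_scales()
  df <- as.data.frame(out)
  df$total <- df$emotion + df$conduct + df$hyper + df$peer
  df
}

#' Endorsement-rate table
#'
#' Percentage of persons endorsing each response category per item, over
#' non-missing responses, for the full sample and (optionally) per group.
#'
#' @param m an \code{sdq_matrix}.
#' @param by_group also tabulate per group level.
#' @return data.frame with columns \code{item_id}, \code{sample} ("full" or a
#'   group level), \code{cat0}, \code{cat1}, \code{cat2} (percentages).
#' @export
endorsement_table <- function(m, by_group = TRUE) {
  if (any(m$n_per_group == 0L)) stop("empty group")
  tab_one <- function(resp, label) {
    pct <- t(apply(resp, 2L, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
      100 * tabulate(x + 1L, nbins = 3L) / length(x)
    }))
    data.frame(item_id = rownames(pct), sample = label,
               cat0 = pct[, 1], cat1 = pct[, 2], cat2 = pct[, 3],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- tab_one(m$responses, "full")
  if (by_group) {
    for (g in levels(m$group))
      out <- rbind(out, tab_one(m$responses[m$group == g, , drop = FALSE], g))
  }
  out
}
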