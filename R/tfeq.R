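#' Default TFEQ-R18 item map
#'
#' Returns the standard assignment of the 18 TFEQ-R18 items to the three
#' subscales: cognitive restraint (CR, 6 items), uncontrolled eating
#' (UE, 9 items) and emotional eating (EE, 3 items), together with each
#' item's response range and reverse-key flag.
#'
#' The 0-100 rescaling formula is range-agnostic, so the per-item ranges are
#' configuration: all items default to a 1-4 response format, and no item is
#' reverse keyed by default. Both can be overridden, e.g. to model an 8-point
#' final item or instruments keyed in the opposite direction.
#'
#' @param item_min,item_max integer scalars or length-18 vectors giving the
#'   response range of each item.
#' @param reverse logical scalar or length-18 vector; `TRUE` marks an item as
#'   reverse keyed (responses are flipped within their range before summing).
#' @return A data.frame with columns `item`, `subscale` (one of `"cr"`,
#'   `"ue"`, `"ee"`), `min`, `max`, `reverse`.
#' @export
#' @examples
#' map <- tfeq_item_map()
#' table(map$subscale)
tfeq_item_map <- function(item_min = 1L, item_max = 4L, reverse = FALSE) {
  subscale <- rep("ue", 18L)
  subscale[c(2L, 11L, 12L, 15L, 16L, 18L)] <- "cr"
  subscale[c(3L, 6L, 10L)] <- "ee"
  map <- data.frame(
    item = seq_len(18L),
    subscale = subscale,
    min = as.integer(rep_len(item_min, 18L)),
    max = as.integer(rep_len(item_max, 18L)),
    reverse = rep_len(as.logical(reverse), 18L)
  )
  validate_item_map(map)
  map
}

validate_item_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("item", "subscale", "min", "max", "reverse") %in% names(map)))
  if (nrow(map) != 18L || !setequal(map$item, 1:18))
    stop("item map must cover items 1..18 exactly once", call. = FALSE)
  if (!all(map$subscale %in% c("cr", "ue", "ee")))
    stop("unknown subscale label in item map", call. = FALSE)
  counts <- table(map$subscale)
  if (counts[["cr"]] != 6L || counts[["ue"]] != 9L || counts[["ee"]] != 3L)
    stop("subscale sizes must be CR=6, UE=9, EE=3", call. = FALSE)
  if (any(map$min >= map$max))
    stop("every item needs min < max", call. = FALSE)
  invisible(map)
}

#' Load a TFEQ item map from a YAML file
#'
#' The file may define `item_min`, `item_max` and `reverse` (scalars or
#' 18-vectors) and optionally a full `subscale` assignment (length-18
#' character vector of "cr"/"ue"/"ee").
#'
#' @param path path to a YAML file.
#' @return An item-map data.frame as from [tfeq_item_map()].
#' @export
read_item_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  map <- tfeq_item_map(
    item_min = cfg$item_min %||% 1L,
    item_max = cfg$item_max %||% 4L,
    reverse = cfg$reverse %||% FALSE
  )
  if (!is.null(cfg$subscale)) {
    map$subscale <- as.character(cfg$subscale)
    validate_item_map(map)
  }
  map
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score one TFEQ-R18 subscale for one participant
#'
#' Sums the (reverse-keyed where flagged) item responses of the requested
#' subscale and rescales the raw sum onto 0-100:
#' `(raw - min_possible) / (max_possible - min_possible) * 100`.
#' The transform maps the subscale minimum to exactly 0 and the maximum to
#' exactly 100 whatever the item ranges are.
#'
#' @param responses integer vector of all 18 item responses, in item order.
#' @param item_map item map from [tfeq_item_map()].
#' @param subscale one of `"cr"`, `"ue"`, `"ee"`.
#' @param prorate if `TRUE`, missing items are imputed with the participant's
#'   mean response on the answered items of the same subscale (keyed scale).
#'   Off by default: missing items are an error.
#' @param participant_id optional label used in error messages.
#' @return Scalar score in \[0, 100\].
#' @export
#' @examples
#' map <- tfeq_item_map()
#' resp <- rep(1L, 18)
#' resp[map$item[map$subscale == "cr"]] <- c(2L, 3L, 1L, 4L, 2L, 3L)
#' score_subscale(resp, map, "cr") # 50
score_subscale <- function(responses, item_map, subscale,
                           prorate = FALSE, participant_id = NULL) {
  subscale <- match.arg(subscale, c("cr", "ue", "ee"))
  validate_item_map(item_map)
  if (length(responses) != 18L)
    stop("expected 18 item responses, got ", length(responses), call. = FALSE)
  rows <- item_map[item_map$subscale == subscale, , drop = FALSE]
  x <- as.numeric(responses[rows$item])
  who <- if (is.null(participant_id)) "" else paste0(" (participant ", participant_id, ")")

  oob <- !is.na(x) & (x < rows$min | x > rows$max | x != round(x))
  if (any(oob))
    stop("out-of-range response on item ", rows$item[which(oob)[1]], who,
         ": ", x[which(oob)[1]], " not in ", rows$min[which(oob)[1]], "..",
         rows$max[which(oob)[1]], call. = FALSE)

  # reverse-keyed items flipped within their range before summation
  x <- ifelse(rows$reverse, rows$min + rows$max - x, x)

  if (anyNA(x)) {
    if (!prorate)
      stop("missing response on item ", rows$item[which(is.na(x))[1]], who,
           "; enable prorate to impute", call. = FALSE)
    if (all(is.na(x)))
      stop("all ", subscale, " items missing", who, call. = FALSE)
    x[is.na(x)] <- mean(x, na.rm = TRUE)
  }

  raw <- sum(x)
  lo <- sum(rows$min)
  hi <- sum(rows$max)
  (raw - lo) / (hi - lo) * 100
}

#' Disinhibited-eating composite
#'
#' The arithmetic mean of the uncontrolled-eating and emotional-eating 0-100
#' subscale scores.
#'
#' @param ue,ee numeric vectors of UE and EE scores in \[0, 100\].
#' @return `(ue + ee) / 2`.
#' @export
disinhibited_composite <- function(ue, ee) {
  ok <- is.na(ue) | (ue >= 0 & ue <= 100)
  ok2 <- is.na(ee) | (ee >= 0 & ee <= 100)
  if (!all(ok) || !all(ok2))
    stop("subscale scores must lie in [0, 100]", call. = FALSE)
  (ue + ee) / 2
}

#' Score a table of TFEQ-R18 responses
#'
#' @param items data.frame with `participant_id` and 18 item columns named
#'   `tfeq_1` .. `tfeq_18` (or any 18 non-id columns in item order).
#' @param item_map item map from [tfeq_item_map()].
#' @param prorate passed to [score_subscale()].
#' @return data.frame with columns `participant_id`, `cr`, `ue`, `ee`,
#'   `disinhibited`.
#' @export
score_tfeq <- function(items, item_map = tfeq_item_map(), prorate = FALSE) {
  stopifnot("participant_id" %in% names(items))
  item_cols <- grep("^tfeq_\\d+$", names(items), value = TRUE)
  if (length(item_cols) == 18L) {
    item_cols <- item_cols[order(as.integer(sub("^tfeq_", "", item_cols)))]
  } else {
    item_cols <- setdiff(names(items), "participant_id")
    if (length(item_cols) != 18L)
      stop("expected 18 item columns, found ", length(item_cols), call. = FALSE)
  }
  mat <- as.matrix(items[item_cols])
  out <- data.frame(
    participant_id = items$participant_id,
    cr = NA_real_, ue = NA_real_, ee = NA_real_
  )
  for (i in seq_len(nrow(mat))) {
    for (s in c("cr", "ue", "ee")) {
      out[[s]][i] <- score_subscale(mat[i, ], item_map, s, prorate = prorate,
                                    participant_id = out$participant_id[i])
    }
  }
  out$disinhibited <- disinhibited_composite(out$ue, out$ee)
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a set of items,
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`,
#' with all variances the unbiased (n-1) estimator.
#'
#' @param item_matrix numeric matrix or data.frame, participants in rows and
#'   items in columns; at least 2 items and 3 participants.
#' @return Scalar alpha, or `NA` with a warning when the total-score variance
#'   is zero (alpha is then undefined).
#' @export
#' @examples
#' set.seed(1)
#' latent <- rnorm(200)
#' items <- sapply(1:5, function(i) latent + rnorm(200, sd = 0.5))
#' cronbach_alpha(items)
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2L) stop("alpha needs at least 2 items", call. = FALSE)
  if (nrow(m) < 3L) stop("alpha needs at least 3 participants", call. = FALSE)
  if (anyNA(m)) stop("item matrix contains missing values", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= .Machine$double.eps * max(abs(m), 1)^2) {
    warning("zero total-score variance: alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
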