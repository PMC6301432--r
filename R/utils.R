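`%||%` <- function(a, b) if (is.null(a)) b else a

# Named sub-generator seeds derived from one master seed so that each
# simulation stage (population, recruitment, dynamics, emission, analysis)
# is independently reproducible. Kept below 2^31 - 1.
.stream_offsets <- c(
  population  = 1L,
  recruitment = 2L,
  dynamics    = 3L,
  emission    = 4L,
  analysis    = 5L
)

stream_seed <- function(master, stream) {
  stopifnot(stream %in% names(.stream_offsets))
  (abs(as.integer(master)) %% 1000000L) * 1009L + .stream_offsets[[stream]]
}

set_stream_seed <- function(master, stream) {
  set.seed(stream_seed(master, stream))
}

#' @keywords internal
new_condition <- function(msg, class) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0 && all(x %in% c(0, 1, TRUE, FALSE))
}

# Uniformly sample k distinct unordered pairs, either within `ids_a`
# (no self-pairs) or across two disjoint id sets. Enumerates when the pair
# universe is small; otherwise rejection-samples with deduplication (first-k
# -distinct of an iid uniform stream is a uniform k-subset).
sample_distinct_pairs <- function(ids_a, ids_b = NULL, k) {
  empty <- data.frame(i = character(0), j = character(0),
                      stringsAsFactors = FALSE)
  if (k <= 0) return(empty)
  within <- is.null(ids_b)
  M <- if (within) length(ids_a) * (length(ids_a) - 1) / 2
       else length(ids_a) * length(ids_b)
  if (k > M) stop("requested more distinct pairs than exist")
  if (M <= 50000) {
    if (within) {
      prs <- t(utils::combn(ids_a, 2))
    } else {
      prs <- as.matrix(expand.grid(ids_a, ids_b, stringsAsFactors = FALSE))
    }
    take <- sample.int(nrow(prs), k)
    return(data.frame(i = as.character(prs[take, 1]),
                      j = as.character(prs[take, 2]),
                      stringsAsFactors = FALSE))
  }
  out_i <- character(0); out_j <- character(0); seen <- character(0)
  while (length(out_i) < k) {
    need <- k - length(out_i)
    m <- ceiling(need * 1.3) + 8
    if (within) {
      a <- sample(ids_a, m, replace = TRUE)
      b <- sample(ids_a, m, replace = TRUE)
      ok <- a != b
      lo <- pmin(a[ok], b[ok]); hi <- pmax(a[ok], b[ok])
    } else {
      lo <- sample(ids_a, m, replace = TRUE)
      hi <- sample(ids_b, m, replace = TRUE)
    }
    key <- paste(lo, hi, sep = "\r")
    keep <- !duplicated(key) & !(key %in% seen)
    lo <- lo[keep]; hi <- hi[keep]; key <- key[keep]
    if (length(lo) > need) {
      lo <- lo[seq_len(need)]; hi <- hi[seq_len(need)]
      key <- key[seq_len(need)]
    }
    out_i <- c(out_i, lo); out_j <- c(out_j, hi); seen <- c(seen, key)
  }
  data.frame(i = out_i, j = out_j, stringsAsFactors = FALSE)
}
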