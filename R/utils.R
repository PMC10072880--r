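#' @importFrom stats rpois rbinom rgeom runif var sd setNames aov TukeyHSD
#' @importFrom stats t.test lm coef predict qt pt ppois dpois p.adjust complete.cases
#' @importFrom utils read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# 1-based position arithmetic on a circle of size L.
wrap_pos <- function(pos, L) {
  ((pos - 1L) %% L) + 1L
}

# Is `pos` inside the 1-based closed interval [start, end]?  Intervals with
# start > end wrap the origin.
in_interval <- function(pos, start, end) {
  if (start <= end) pos >= start & pos <= end else pos >= start | pos <= end
}

# Membership of positions in any row of an interval table (columns start, end).
in_any_interval <- function(pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | in_interval(pos, intervals$start[i], intervals$end[i])
  }
  hit
}

# Truncated-at-1 Poisson draws (family sizes must be >= 1).
rtpois1 <- function(n, mean) {
  out <- rpois(n, mean)
  while (any(out < 1L)) {
    i <- out < 1L
    out[i] <- rpois(sum(i), mean)
  }
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
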