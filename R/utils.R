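# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without touching the caller's
# RNG state. All package randomness flows through this helper.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# stopifnot with a readable message
check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == round(x)

# Merge possibly overlapping/bookended half-open intervals given as a
# data.frame with chrom/start/end. Returns merged intervals, sorted.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    s <- d$start[1]; e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= e) e <- max(e, d$end[i])
      else { out[[length(out) + 1L]] <- c(ch, s, e); s <- d$start[i]; e <- d$end[i] }
    }
    out[[length(out) + 1L]] <- c(ch, s, e)
  }
  data.frame(chrom = vapply(out, `[`, "", 1L),
             start = as.numeric(vapply(out, `[`, "", 2L)),
             end   = as.numeric(vapply(out, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# Intersection of two sets of disjoint half-open intervals.
intersect_intervals <- function(a, b) {
  res <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    x <- a[a$chrom == ch, , drop = FALSE]
    y <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y))) {
      s <- max(x$start[i], y$start[j]); e <- min(x$end[i], y$end[j])
      if (s < e) res[[length(res) + 1L]] <- data.frame(chrom = ch, start = s, end = e,
                                                       stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  merge_intervals(do.call(rbind, res))
}
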