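# Shared fixtures and independent brute-force oracles.

# All permutations of 1..n (n <= 7), recursively; independent of any
# package code.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- append(sub[s, ], n, after = pos - 1L)
    }
  }
  out
}

# Brute-force Mann-Kendall score by explicit double loop.
brute_mk_score <- function(x) {
  s <- 0L
  n <- length(x)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- s + sign(x[j] - x[i])
    }
  }
  as.integer(s)
}

# A hand-built grid city: g x g unit origin cells, destination blocks of
# b x b cells, no straddlers.  Built directly from coordinates, not via
# the generator, so generator tests have an independent reference.
toy_grid <- function(g, b) {
  og <- list()
  for (r in 0:(g - 1L)) {
    for (cc in 0:(g - 1L)) {
      og[[sprintf("O%03d", r * g + cc + 1L)]] <-
        cbind(c(cc, cc + 1, cc + 1, cc), c(r, r, r + 1, r + 1))
    }
  }
  gd <- g %/% b
  dg <- list()
  for (r in 0:(gd - 1L)) {
    for (cc in 0:(gd - 1L)) {
      dg[[sprintf("D%03d", r * gd + cc + 1L)]] <-
        cbind(c(cc, cc + 1, cc + 1, cc) * b, c(r, r, r + 1, r + 1) * b)
    }
  }
  list(origins = partition_set("origin", og, validate = FALSE),
       destinations = partition_set("destination", dg, validate = FALSE))
}

# Closed-interval bbox overlap: the exact share-any-point predicate for
# axis-aligned rectangles, written independently of the package geometry.
brute_rect_pairs <- function(origins, destinations) {
  ob <- origins$bboxes
  db <- destinations$bboxes
  out <- NULL
  for (i in seq_along(origins$ids)) {
    for (j in seq_along(destinations$ids)) {
      if (ob[i, 1] <= db[j, 3] && db[j, 1] <= ob[i, 3] &&
          ob[i, 2] <= db[j, 4] && db[j, 2] <= ob[i, 4]) {
        out <- rbind(out, c(origins$ids[i], destinations$ids[j]))
      }
    }
  }
  data.frame(origin_id = out[, 1], destination_id = out[, 2],
             stringsAsFactors = FALSE)
}

# Canonical string form of a pair set, for set comparison.
pair_key <- function(df) sort(paste(df$origin_id, df$destination_id))

# A small deterministic edge list over the toy grid.
toy_visits <- function(city, period, seed = 7) {
  set.seed(seed)
  o <- city$origins$ids
  d <- city$destinations$ids
  grid <- expand.grid(origin_id = o, destination_id = d,
                      stringsAsFactors = FALSE)
  grid$period <- period
  grid$mean_daily_visits <- round(runif(nrow(grid), 0, 20), 2)
  grid
}
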