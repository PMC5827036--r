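# Shared fixtures, built in code at test time.

# default 8-cell tissue, built once per test session
default_tissue <- local({
  tis <- NULL
  function() {
    if (is.null(tis)) tis <<- generate_fixture_tissue(seed = 1)
    tis
  }
})

# one square cell with 4 corner receptors: easy closed-form geometry
square_cell_tissue <- function(affinity = 1, capacity = 5,
                               width = 40, height = 40) {
  b <- rbind(c(15, 15), c(25, 15), c(25, 25), c(15, 25))
  rec <- data.frame(x = c(15, 25, 25, 15), y = c(15, 15, 25, 25),
                    affinity = affinity, capacity = capacity)
  tissue_domain(width, height, list(list(id = 1L, boundary = b,
                                         receptors = rec)))
}

# pure-R ray-casting oracle; boundary handled by the caller's tolerance
oracle_point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  inside <- FALSE
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
    if ((yi > p[2]) != (yj > p[2]) &&
        p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi)
      inside <- !inside
  }
  inside
}

# exhaustive nearest-receptor oracle (strict < r_min)
oracle_nearest_receptor <- function(p, rec, r_min) {
  d <- sqrt((rec$x - p[1])^2 + (rec$y - p[2])^2)
  ok <- which(d < r_min)
  if (length(ok) == 0) return(NA_integer_)
  ok[order(d[ok], ok)][1]
}

# a small, fast config for engine tests
quick_config <- function(...) {
  defaults <- list(L_total = 300, scheme = "fast", dt = 0.1, T_end = 1800,
                   record_times_min = c(1, 5, 10, 20, 30), seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
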