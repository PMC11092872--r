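# Shared fixtures: small geometries and chains built in code.

geom8 <- lattice_geometry(c(8, 8, 8))

trimer_straight <- function(g = geom8)
  polymer_chain(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)), g)

trimer_L <- function(g = geom8)
  polymer_chain(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1)), g)

square4 <- function(g = geom8)
  polymer_chain(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)), g)

# straight bulk molecule along +z starting at `at`
straight_molecule <- function(species, at, n_b) {
  list(species = species,
       sites = cbind(at[1], at[2], at[3] + seq_len(n_b) - 1L))
}

# random self-avoiding walk grown step by step (unwrapped), for fixtures
random_saw <- function(g, n, start = c(0, 0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    co <- matrix(start, 1)
    used <- as.character(site_index(matrix(start, 1), g))
    ok <- TRUE
    for (i in seq_len(n - 1)) {
      dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
      dirs <- dirs[sample.int(6), , drop = FALSE]
      placed <- FALSE
      for (k in 1:6) {
        cand <- co[nrow(co), ] + dirs[k, ]
        key <- as.character(site_index(matrix(cand, 1), g))
        if (!key %in% used) {
          co <- rbind(co, cand)
          used <- c(used, key)
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(polymer_chain(co, g))
  }
}
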