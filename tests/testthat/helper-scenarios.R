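## Shared fixtures: scenarios are generated once per test session and
## cached, since several test files exercise the same locus.

.scn_cache <- new.env(parent = emptyenv())

get_scenario <- function(name, seed = 1L, ...) {
  key <- paste(name, seed, ...)
  if (!exists(key, envir = .scn_cache)) {
    assign(key, generate_scenario(scenario_spec(name, seed = seed, ...)),
           envir = .scn_cache)
  }
  get(key, envir = .scn_cache)
}

## a tiny genome string with known content, used across signal tests
make_genome <- function(seqs) {
  gs <- Biostrings::DNAStringSet(unlist(seqs))
  names(gs) <- names(seqs)
  gs
}

## exhaustive Hamming-distance hexamer scan: the independent oracle for
## scan_pas_motif (scans every hexamer, filters by distance window)
oracle_pas_scan <- function(seq_chars, cleavage_pos, min_up, max_up) {
  hits <- list()
  for (m_end in seq_along(seq_chars)) {
    d <- cleavage_pos - m_end
    if (d < min_up || d > max_up) next
    if (m_end < 6) next
    hex <- seq_chars[(m_end - 5):m_end]
    if (any(!hex %in% c("A", "C", "G", "T"))) next
    mm <- sum(hex != strsplit("AATAAA", "")[[1]])
    if (mm <= 1) {
      hits[[length(hits) + 1]] <- list(d = d, mm = mm,
                                       seq = paste(hex, collapse = ""))
    }
  }
  hits
}

## brute-force single-linkage clustering by pairwise connectivity
oracle_cluster <- function(pos, gap) {
  n <- length(pos)
  if (!n) return(integer(0))
  adj <- abs(outer(pos, pos, "-")) <= gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}
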