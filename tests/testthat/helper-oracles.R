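# Shared test substrate: memoized synthetic genomes and independent
# brute-force oracles the implementations are checked against.

.sim_cache <- new.env(parent = emptyenv())

get_sim <- function(seed, config = NULL) {
  key <- paste0("s", seed, if (!is.null(config)) "_custom")
  if (!is.null(config)) return(generate_mitogenome(config))
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- generate_mitogenome(simulation_config(seed = seed))
  .sim_cache[[key]]
}

rand_seq <- function(n, p = c(A = .3, C = .2, G = .2, T = .3)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# naive reverse complement, independent of the package's Biostrings route
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# RSCU by explicit family enumeration
oracle_rscu <- function(counts, partition) {
  out <- setNames(rep(NA_real_, length(counts)), names(counts))
  for (fam in unique(partition$family_of)) {
    members <- names(partition$family_of)[partition$family_of == fam]
    tot <- sum(counts[members])
    if (tot == 0) next
    for (cd in members) out[cd] <- counts[cd] * length(members) / tot
  }
  out[order(names(out))]
}

# maximal tandem arrays by exhaustive scan
oracle_microsats <- function(seq, u, min_copies) {
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  hits <- list()
  for (start in seq_len(n)) {
    if (start + u * min_copies - 1L > n) break
    unit <- paste(b[start:(start + u - 1L)], collapse = "")
    if (u > 1L && length(unique(b[start:(start + u - 1L)])) == 1L) next
    copies <- 1L
    while (start + (copies + 1L) * u - 1L <= n &&
           paste(b[(start + copies * u):(start + (copies + 1L) * u - 1L)],
                 collapse = "") == unit) copies <- copies + 1L
    if (copies < min_copies) next
    # maximal: no full-unit extension left, and not a phase-shifted suffix
    # of an equal array starting earlier in the same periodic region
    left_ok <- start - u < 1L ||
      paste(b[(start - u):(start - 1L)], collapse = "") != unit
    prev_ok <- start - 1L < 1L || b[start - 1L] != b[start + u - 1L]
    if (left_ok && prev_ok)
      hits[[length(hits) + 1L]] <- list(start = start, copies = copies,
                                        unit = unit)
  }
  hits
}

# repeated substrings >= min_len occurring >= 2 times, suppressing those
# wholly covered by a longer retained repeat (direct dictionary method)
oracle_direct_repeats <- function(seq, min_len) {
  n <- nchar(seq)
  reps <- list()
  for (len in seq(min_len, n - 1L)) {
    starts <- 1:(n - len + 1L)
    subs <- substring(seq, starts, starts + len - 1L)
    grp <- split(starts, subs)
    grp <- grp[lengths(grp) >= 2L]
    for (u in names(grp)) reps[[u]] <- grp[[u]]
  }
  if (length(reps) == 0L) return(list())
  units <- names(reps)
  keep <- rep(TRUE, length(units))
  for (i in seq_along(units)) {
    for (j in seq_along(units)) {
      if (nchar(units[j]) <= nchar(units[i])) next
      offs <- gregexpr(units[i], units[j], fixed = TRUE)[[1]]
      offs <- offs[offs > 0L]
      if (length(offs) == 0L) next
      covered <- vapply(reps[[i]], function(s)
        any(vapply(reps[[j]], function(t) any(s - t + 1L == offs),
                   logical(1))), logical(1))
      if (all(covered)) { keep[i] <- FALSE; break }
    }
  }
  lapply(which(keep), function(i)
    list(unit = units[i], occ = reps[[i]]))
}

compare_arms <- function(folded, manifest_arms) {
  for (a in c("acceptor", "dhu", "anticodon_arm", "tpsic")) {
    want <- manifest_arms[[a]]
    got <- folded[[a]]
    if (!identical(isTRUE(want$present), isTRUE(got$present))) return(FALSE)
    if (isTRUE(want$present)) {
      if (!identical(unname(want$pairs[, 1]), unname(got$pairs[, "p5"])) ||
          !identical(unname(want$pairs[, 2]), unname(got$pairs[, "p3"])))
        return(FALSE)
    }
  }
  TRUE
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
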