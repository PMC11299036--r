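# Nei-Gojobori (1986) counting tables, built once per session from the
# standard genetic code and cached.
#
# Conventions (standard NG86 practice):
#  * fractional synonymous sites per codon position = synonymous changes /
#    non-stop changes at that position (changes to stop codons are not
#    countable); each position contributes one site, so S + N = 3 per codon
#  * observed differences between two codons are averaged over all minimal
#    mutational pathways that avoid stop codons, with equal weights; if every
#    pathway passes through a stop, all pathways are used and steps into a
#    stop count as nonsynonymous

.codonTables <- function() {
  if (!is.null(.ph_cache$codon)) return(.ph_cache$codon)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  sense <- codons[gc != "*"]

  neighbors <- function(cd, pos) {
    vapply(setdiff(bases, substr(cd, pos, pos)),
           function(b) { x <- cd; substr(x, pos, pos) <- b; x }, "")
  }

  S <- setNames(numeric(length(sense)), sense)
  synOpts <- nsynOpts <- setNames(vector("list", length(sense)), sense)
  for (cd in sense) {
    s <- 0
    so <- list(); no <- list()
    for (pos in 1:3) {
      alt <- neighbors(cd, pos)
      ok <- gc[alt] != "*"
      if (any(ok))
        s <- s + sum(gc[alt[ok]] == gc[cd]) / sum(ok)
      for (a in alt[ok]) {
        rec <- c(pos = pos, base = substr(a, pos, pos))
        if (gc[a] == gc[cd]) so[[length(so) + 1]] <- rec
        else no[[length(no) + 1]] <- rec
      }
    }
    S[cd] <- s
    synOpts[[cd]] <- so
    nsynOpts[[cd]] <- no
  }

  # pathway-averaged Sd/Nd for every ordered sense-codon pair
  nn <- length(sense)
  Sd <- Nd <- matrix(0, nn, nn, dimnames = list(sense, sense))
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  pathCount <- function(c1, c2) {
    s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
    dif <- which(s1 != s2)
    d <- length(dif)
    if (d == 0) return(c(0, 0))
    perms <- switch(d, list(1L), perms2, perms3)
    res <- matrix(NA_real_, length(perms), 2)
    blocked <- logical(length(perms))
    for (pi in seq_along(perms)) {
      cur <- c1; sd <- 0; nd <- 0; hit_stop <- FALSE
      for (step in dif[perms[[pi]]]) {
        nxt <- cur
        substr(nxt, step, step) <- s2[step]
        if (gc[nxt] == "*") { hit_stop <- TRUE; nd <- nd + 1 }
        else if (!hit_stop && gc[nxt] == gc[cur]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      res[pi, ] <- c(sd, nd)
      blocked[pi] <- hit_stop
    }
    use <- if (all(blocked)) rep(TRUE, length(perms)) else !blocked
    colMeans(res[use, , drop = FALSE])
  }
  for (i in seq_len(nn)) for (j in seq_len(nn)) {
    if (i == j) next
    sn <- pathCount(sense[i], sense[j])
    Sd[i, j] <- sn[1]; Nd[i, j] <- sn[2]
  }

  # options that also preserve the codon's fractional synonymous-site count
  # (used by the paralog generator so divergence targets are hit exactly)
  applyOpt <- function(cd, op) {
    substr(cd, as.integer(op["pos"]), as.integer(op["pos"])) <- op["base"]
    cd
  }
  spFilter <- function(cd, opts)
    Filter(function(op) {
      nxt <- applyOpt(cd, op)
      isTRUE(abs(S[nxt] - S[cd]) < 1e-9)
    }, opts)
  spSyn <- mapply(spFilter, sense, synOpts, SIMPLIFY = FALSE)
  spNsyn <- mapply(spFilter, sense, nsynOpts, SIMPLIFY = FALSE)

  .ph_cache$codon <- list(geneticCode = gc, sense = sense, S = S,
                          Sd = Sd, Nd = Nd,
                          synOpts = synOpts, nsynOpts = nsynOpts,
                          spSyn = spSyn, spNsyn = spNsyn)
  .ph_cache$codon
}

# split a gap-free coding string into codons
.toCodons <- function(s) {
  n <- nchar(s) %/% 3
  substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
}
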