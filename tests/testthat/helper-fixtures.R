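# shared fixtures: file paths, reference sequences, tiny builders

cav1_fasta <- function() {
  system.file("extdata", "cav1_utr_reporter.fa", package = "mirseed")
}

mirna_fasta <- function() {
  system.file("extdata", "mature_mirnas.fa", package = "mirseed")
}

# mature miR-199a-5p (miRBase)
MIR199A5P <- "CCCAGUGUUCAGACUACCUGUUC"

# mature sequences with five distinct seeds, used as scan decoys
decoy_mirnas <- function() {
  c(`miR-X`   = MIR199A5P,
    `dec-21`  = "UAGCUUAUCAGACUGAUGUUGA",
    `dec-let7`= "UGAGGUAGUAGGUUGUAUAGUU",
    `dec-122` = "UGGAGUGUGACAAUGGUGUUUG",
    `dec-27a` = "UUCACAGUGGCUAAGUUCUGC")
}

# random DNA string
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny de_table builder for threshold/filter tests
make_de <- function(ids, aveexpr, logfc, p = rep(1e-4, length(ids)),
                    adjp = p) {
  out <- data.frame(feature_id = ids, AveExpr = aveexpr, logFC = logfc,
                    t_mod = sign(logfc) * 5, p = p, adjP = adjp,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

# naive O(n*m) sliding-window motif scan: the independent oracle
naive_scan <- function(seqs, motif) {
  w <- nchar(motif)
  rows <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    for (i in seq_len(max(0L, nchar(s) - w + 1L))) {
      if (substr(s, i, i + w - 1L) == motif) {
        rows[[length(rows) + 1L]] <- data.frame(utr_id = id, start = i - 1L,
                                                end = i - 1L + w)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(utr_id = character(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, rows)
}

# brute-force hypergeometric upper tail: exact combinatorial sum
hyper_upper_oracle <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force BH step-up: adj_i = min over j >= i of min(1, m p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  adj
}

# brute-force running-sum ES: literal walk down the list
es_oracle <- function(ids, metric, gene_set, exponent) {
  hits <- ids %in% gene_set
  w <- abs(metric)^exponent
  run <- 0
  best <- 0
  denom_hit <- sum(w[hits])
  denom_miss <- sum(!hits)
  for (i in seq_along(ids)) {
    run <- run + if (hits[i]) w[i] / denom_hit else -1 / denom_miss
    if (abs(run) > abs(best)) best <- run
  }
  best
}
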