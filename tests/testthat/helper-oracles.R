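# Independent oracles and small fixture builders shared across tests.

# O(n^3) brute-force UPGMA: recomputes every inter-cluster average distance
# from the full pairwise matrix at each step. Returns merge heights in the
# order clusters are formed (non-decreasing for average linkage).
upgma_oracle_heights <- function(points) {
  d <- as.matrix(dist(points))
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- Inf
    bi <- bj <- NA
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best) {
          best <- avg
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Pairwise-comparison AUC: fraction of (positive, negative) pairs where the
# positive outscores the negative, ties counted half.
auc_oracle <- function(pos_scores, neg_scores) {
  s <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos_scores) * length(neg_scores))
}

expr_to_mat <- function(tbl) cnssig:::expr_to_matrix(tbl)

# Matrix -> wide tibble (probe_id + sample columns); names filled if absent.
matrix_tbl <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  cnssig:::matrix_to_expr(m)
}

# Two-entity toy codeset for classification unit tests.
toy_codeset <- function() {
  codeset(
    name = "toy",
    entities = list(
      E1 = list(supratentorial = c("A1", "A2"), infratentorial = "A1"),
      E2 = list(supratentorial = c("B1", "B2"))
    ),
    housekeeping = c("HK1", "HK2"),
    glioma_panel = c("G1", "G2", "G3")
  )
}

# Wide log2 tibble from a probes x samples matrix given as named rows.
log2_tbl <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  dplyr::mutate(
    tibble::as_tibble(m, .name_repair = "minimal"),
    probe_id = rownames(m), .before = 1
  )
}

# Tiny RCC record table covering all CodeClasses of a codeset.
toy_records <- function(cs, counts = NULL) {
  cls <- cnssig:::codeset_classes(cs)
  tibble::tibble(
    code_class = cls$code_class,
    probe = cls$probe,
    accession = paste0("SYN_", cls$probe),
    count = counts %||% seq_len(nrow(cls))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
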