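# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Minimal per-cell data.frame whose defaults pass every QC rule.
makeCellDF <- function(n = 1L, compartment = "epithelial", x = 10, y = 10,
                       nucleus_count = 1L, area_nucleus = 120,
                       area_membrane = 200, area_cytoplasm = 300,
                       cell_area = 700, quality_score = 0.95,
                       cell_id = sprintf("c%03d", seq_len(n))) {
  data.frame(cell_id = cell_id, x = rep_len(x, n), y = rep_len(y, n),
             compartment = rep_len(compartment, n),
             nucleus_count = rep_len(nucleus_count, n),
             area_nucleus = rep_len(area_nucleus, n),
             area_membrane = rep_len(area_membrane, n),
             area_cytoplasm = rep_len(area_cytoplasm, n),
             cell_area = rep_len(cell_area, n),
             quality_score = rep_len(quality_score, n),
             stringsAsFactors = FALSE)
}

makeTable <- function(cells, intensities = NULL, markers = c("p63", "CK5"),
                      ...) {
  if (is.null(intensities))
    intensities <- matrix(1, nrow(cells), length(markers),
                          dimnames = list(NULL, markers))
  CellTable(cells, intensities, ...)
}

# Scaled-down core for fast integration tests.
smallCoreConfig <- function(seed = 1L, imageSize = 800L, nGlands = 3L,
                            glandRadius = c(90, 120), ...) {
  simCoreConfig(imageSize = imageSize, nGlands = nGlands,
                glandRadius = glandRadius, seed = seed, ...)
}

# Core config in the 4-pooled-sd separation regime, dense enough for tight
# sensitivity/specificity estimates.
fourSdCoreConfig <- function(seed = 1L, imageSize = 2000L, nGlands = 10L) {
  sd0 <- 0.7
  one <- list(bg = c(mean = 2, sd = sd0), fg = c(mean = 2 + 4 * sd0, sd = sd0))
  mp <- setNames(rep(list(one), 8),
                 c("p63", "CK5", "AMACR", "CD3", "CD4", "CD8", "CD68", "FOXP3"))
  simCoreConfig(imageSize = imageSize, nGlands = nGlands, ceCellSpacing = 20,
                basalSpacing = 15, markerParams = mp, seed = seed)
}

# Match classified labels against generator truth for epithelial cells.
epithelialConfusion <- function(table, truth, column = "cell_type") {
  df <- cellData(table)
  tr <- truth$cells[match(df$cell_id, truth$cells$cell_id), ]
  epi <- tr$true_type %in% c("CE", "N-CE")
  list(sens = mean(df[[column]][epi & tr$true_type == "N-CE"] == "N-CE"),
       spec = mean(df[[column]][epi & tr$true_type == "CE"] == "CE"),
       acc = mean(df[[column]][epi] == tr$true_type[epi]))
}

# Independent point-to-polyline distance: plain double loop over segments,
# written separately from the package implementation.
bruteMinDistToPolyline <- function(pts, poly) {
  apply(as.matrix(pts), 1, function(p) {
    dmin <- Inf
    for (j in seq_len(nrow(poly) - 1)) {
      a <- poly[j, ]; b <- poly[j + 1, ]
      v <- b - a
      L2 <- sum(v^2)
      u <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * v) / L2))
      dmin <- min(dmin, sqrt(sum((p - (a + u * v))^2)))
    }
    dmin
  })
}

# Brute-force minimum spanning tree weight by enumerating all labeled
# trees on n vertices via Pruefer sequences (n^(n-2) trees).
bruteMSTWeight <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3, n <= 6)
  decode <- function(pr) {
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, 0, 2)
    for (v in pr) {
      leaf <- which(degree == 1L)[1]
      edges <- rbind(edges, c(leaf, v))
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    rbind(edges, last)
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- decode(seqs[i, ])
    best <- min(best, sum(d[e]))
  }
  best
}

rigidTransform <- function(pts, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(as.matrix(pts) %*% t(R), 2, -shift)
}
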