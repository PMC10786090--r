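# Build a 62-channel extended 10-20 montage on the unit sphere and check
# the adjacency properties we document (connected, 2-10 neighbors at 1.3x
# median nearest-neighbor distance).
rows <- list(
  list(prefix = "Fp",  a =  72, labs = c("Fp1" = -18, "Fpz" = 0, "Fp2" = 18)),
  list(prefix = "AF",  a =  54, labs = c("AF7" = -54, "AF3" = -22, "AF4" = 22, "AF8" = 54)),
  list(prefix = "F",   a =  36, labs = c("F7" = -72, "F5" = -54, "F3" = -36, "F1" = -18,
                                         "Fz" = 0, "F2" = 18, "F4" = 36, "F6" = 54, "F8" = 72)),
  list(prefix = "FC",  a =  18, labs = c("FT7" = -72, "FC5" = -54, "FC3" = -36, "FC1" = -18,
                                         "FCz" = 0, "FC2" = 18, "FC4" = 36, "FC6" = 54, "FT8" = 72)),
  list(prefix = "C",   a =   0, labs = c("T7" = -72, "C5" = -54, "C3" = -36, "C1" = -18,
                                         "Cz" = 0, "C2" = 18, "C4" = 36, "C6" = 54, "T8" = 72)),
  list(prefix = "CP",  a = -18, labs = c("TP7" = -72, "CP5" = -54, "CP3" = -36, "CP1" = -18,
                                         "CPz" = 0, "CP2" = 18, "CP4" = 36, "CP6" = 54, "TP8" = 72)),
  list(prefix = "P",   a = -36, labs = c("P7" = -72, "P5" = -54, "P3" = -36, "P1" = -18,
                                         "Pz" = 0, "P2" = 18, "P4" = 36, "P6" = 54, "P8" = 72)),
  list(prefix = "PO",  a = -54, labs = c("PO7" = -54, "PO5" = -40, "PO3" = -24, "POz" = 0,
                                         "PO4" = 24, "PO6" = 40, "PO8" = 54)),
  list(prefix = "O",   a = -72, labs = c("O1" = -18, "Oz" = 0, "O2" = 18))
)
deg2rad <- function(d) d * pi / 180
pos <- do.call(rbind, lapply(rows, function(r) {
  a <- deg2rad(r$a)           # midline angle from vertex, + = anterior
  b <- deg2rad(unname(r$labs))  # lateral angle, + = right
  # vertex (0,0,1) tilted by a about the x-axis (toward +y = nose), then by b
  # about the y-axis (toward +x = right ear)
  v0 <- cbind(0, sin(a), cos(a))
  t(sapply(b, function(bb) {
    c(v0[1] * cos(bb) + v0[3] * sin(bb), v0[2], -v0[1] * sin(bb) + v0[3] * cos(bb))
  }))
}))
labels <- unlist(lapply(rows, function(r) names(r$labs)))
stopifnot(length(labels) == 62, nrow(pos) == 62, !anyDuplicated(labels))
m <- data.frame(label = labels, x = round(pos[, 1], 6), y = round(pos[, 2], 6),
                z = round(pos[, 3], 6))
d <- as.matrix(dist(m[, c("x", "y", "z")]))
diag(d) <- Inf
nn <- apply(d, 1, min)
thr <- 1.3 * median(nn)
adj <- d <= thr
deg <- rowSums(adj)
cat("threshold:", thr, "\n")
cat("degree range:", range(deg), "\n")
# connectivity by BFS
seen <- logical(62); seen[1] <- TRUE; front <- 1
while (length(front)) {
  nxt <- which(apply(adj[front, , drop = FALSE], 2, any) & !seen)
  seen[nxt] <- TRUE; front <- nxt
}
cat("connected:", all(seen), "\n")
print(table(deg))
write.table(m, "inst/extdata/montage62.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
# also check the evenly-spaced 16-channel subset used at reduced dimensions
idx <- round(seq(1, 62, length.out = 16))
d2 <- d[idx, idx]; nn2 <- apply(d2, 1, min); thr2 <- 1.3 * median(nn2)
adj2 <- d2 <= thr2
cat("16-ch subset degrees:", range(rowSums(adj2)), "\n")
seen <- logical(16); seen[1] <- TRUE; front <- 1
while (length(front)) {
  nxt <- which(apply(adj2[front, , drop = FALSE], 2, any) & !seen)
  seen[nxt] <- TRUE; front <- nxt
}
cat("16-ch subset connected:", all(seen), "\n")
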