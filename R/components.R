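# 8-connected component labeling on a logical matrix, via an explicit
# pixel-adjacency graph (diagonal neighbors count as connected, matching
# how a thresholded blob is read in segmentation work).
label_components <- function(mask) {
  mask <- as_binary_mask(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[fg] <- seq_along(fg)
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    src <- id[fg[ok]]
    keep <- nb > 0L
    if (any(keep)) edges <- c(edges, rbind(src[keep], nb[keep]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

# Per-component statistics of a label matrix, optionally weighted by an
# intensity field (mass = sum of weights over the component).
component_stats <- function(lab, weights = NULL) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L)
    return(data.frame(id = integer(0), area_px = integer(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      r0 = integer(0), c0 = integer(0),
                      r1 = integer(0), c1 = integer(0),
                      mass = numeric(0)))
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  w <- if (is.null(weights)) rep(1, length(idx)) else weights[idx]
  agg <- function(v, f) as.numeric(tapply(v, comp, f))
  data.frame(
    id = ids,
    area_px = as.integer(agg(rep(1L, length(idx)), sum)),
    centroid_r = agg(rr, mean) - 1,  # 0-based geometry
    centroid_c = agg(cc, mean) - 1,
    r0 = as.integer(agg(rr, min)) - 1L,
    c0 = as.integer(agg(cc, min)) - 1L,
    r1 = as.integer(agg(rr, max)),   # half-open upper bounds
    c1 = as.integer(agg(cc, max)),
    mass = agg(w, sum)
  )
}
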