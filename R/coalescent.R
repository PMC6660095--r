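# Multispecies-coalescent machinery used by the synthetic radiation
# generator: windows are simulated as independent coalescent loci whose
# lineages track the branches of a dated species tree, with optional
# admixture pulses implemented as backward-in-time lineage reassignment.

# Precompute, from a dated (ultrametric, generations) species tree, the
# arrays the per-window simulation needs: node times, children, parents,
# and the tip node of each taxon.
species_tree_plan <- function(tree) {
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be fully resolved")
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  time <- max(depth[seq_len(n_tip)]) - depth
  if (any(abs(time[seq_len(n_tip)]) > 1e-6 * max(time))) {
    stop("species tree must be ultrametric (branch lengths in generations)")
  }
  time[seq_len(n_tip)] <- 0
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])
  internal <- order(time[-(seq_len(n_tip))]) + n_tip
  list(
    tree = tree, n_tip = n_tip, time = time, parent = parent,
    children = children, internal = internal,
    tip_of = setNames(seq_len(n_tip), tree$tip.label),
    root = internal[length(internal)]
  )
}

# Species-tree branch occupied by the lineage of `taxon` at time t ago.
pop_at_time <- function(plan, taxon, t) {
  v <- plan$tip_of[[taxon]]
  while (!is.na(plan$parent[v]) && plan$time[plan$parent[v]] <= t) {
    v <- plan$parent[v]
  }
  v
}

# Event table for msc_genealogy: species-tree merges plus optional
# admixture pulses, in time order. `pulses`: data frame with columns
# time, from_pop (branch holding the recipient taxon's lineages: pulses
# are backward-in-time reassignments), to_pop (donor branch), fraction.
msc_events <- function(plan, pulses = NULL) {
  time <- plan$time[plan$internal]
  type <- rep(1L, length(time))  # 1 = merge, 2 = pulse
  node <- plan$internal
  from <- to <- rep(NA_integer_, length(time))
  frac <- rep(NA_real_, length(time))
  if (!is.null(pulses) && nrow(pulses)) {
    time <- c(time, pulses$time)
    type <- c(type, rep(2L, nrow(pulses)))
    node <- c(node, rep(NA_integer_, nrow(pulses)))
    from <- c(from, pulses$from_pop)
    to <- c(to, pulses$to_pop)
    frac <- c(frac, pulses$fraction)
  }
  o <- order(time)
  list(time = time[o], type = type[o], node = node[o],
       from = from[o], to = to[o], frac = frac[o], n = length(o))
}

# Simulate one gene genealogy under the species tree. `tip_pop`: species
# tree node per sampled haploid lineage; `ne`: diploid size per species
# tree node (already scaled by the window's Ne multiplier); `events`:
# from msc_events(). Returns node times and children of a fully
# coalesced genealogy with tips 1..n.
msc_genealogy <- function(plan, tip_pop, ne, events) {
  n <- length(tip_pop)
  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  child1 <- integer(n_nodes)
  child2 <- integer(n_nodes)
  pop <- c(tip_pop, integer(n - 1L))
  alive <- seq_len(n)
  nxt <- n
  n_sp <- length(plan$time)
  cnt <- tabulate(tip_pop, n_sp)  # lineages per species-tree branch
  inv2ne <- 1 / (2 * ne)
  t <- 0
  for (e in c(seq_len(events$n), NA)) {
    t_end <- if (is.na(e)) Inf else events$time[e]
    repeat {
      if (length(alive) <= 1L) break
      rates <- cnt * (cnt - 1L) * 0.5 * inv2ne
      tot <- sum(rates)
      if (tot == 0) break
      dt <- rexp(1, tot)
      if (t + dt >= t_end) break
      t <- t + dt
      p_sel <- which.max(cumsum(rates) >= runif(1) * tot)
      in_p <- alive[pop[alive] == p_sel]
      pick <- in_p[sample.int(length(in_p), 2L)]
      nxt <- nxt + 1L
      time[nxt] <- t
      child1[nxt] <- pick[1]
      child2[nxt] <- pick[2]
      alive <- c(alive[!(alive %in% pick)], nxt)
      pop[nxt] <- p_sel
      cnt[p_sel] <- cnt[p_sel] - 1L
    }
    if (length(alive) <= 1L) break
    if (is.na(e)) break
    t <- t_end
    if (events$type[e] == 1L) {
      kids <- plan$children[[as.character(events$node[e])]]
      sel <- pop[alive] %in% kids
      pop[alive][sel] <- events$node[e]
      cnt[events$node[e]] <- cnt[events$node[e]] + sum(cnt[kids])
      cnt[kids] <- 0L
    } else {
      idx <- alive[pop[alive] == events$from[e]]
      if (length(idx)) {
        move <- idx[runif(length(idx)) < events$frac[e]]
        pop[move] <- events$to[e]
        cnt[events$from[e]] <- cnt[events$from[e]] - length(move)
        cnt[events$to[e]] <- cnt[events$to[e]] + length(move)
      }
    }
  }
  if (length(alive) > 1L) stop("genealogy failed to coalesce")  # unreachable
  list(n = n, time = time[seq_len(nxt)],
       child1 = child1[seq_len(nxt)], child2 = child2[seq_len(nxt)])
}

# Tip-descendant indicator matrix (nodes x tips) of a genealogy.
genealogy_descendants <- function(gen) {
  n_nodes <- length(gen$time)
  desc <- matrix(FALSE, n_nodes, gen$n)
  desc[cbind(seq_len(gen$n), seq_len(gen$n))] <- TRUE
  for (v in (gen$n + 1L):n_nodes) {
    desc[v, ] <- desc[gen$child1[v], ] | desc[gen$child2[v], ]
  }
  desc
}

# Drop infinite-sites mutations on a genealogy: returns a logical matrix
# (mutations x tips) of derived-allele carriage plus 0-based positions
# within [0, locus_bp). At most one mutation per position.
genealogy_mutations <- function(gen, mu, locus_bp) {
  n_nodes <- length(gen$time)
  parent <- integer(n_nodes)
  for (v in (gen$n + 1L):n_nodes) {
    parent[gen$child1[v]] <- v
    parent[gen$child2[v]] <- v
  }
  idx <- which(parent > 0L)
  bl <- numeric(n_nodes)
  bl[idx] <- gen$time[parent[idx]] - gen$time[idx]
  total <- sum(bl)
  n_mut <- rpois(1, mu * locus_bp * total)
  n_mut <- min(n_mut, locus_bp)  # finite sites: one mutation per position
  if (n_mut == 0) {
    return(list(pos = integer(0),
                carriers = matrix(FALSE, 0, gen$n)))
  }
  branch <- sample.int(n_nodes, n_mut, replace = TRUE, prob = bl)
  pos <- sort(sample.int(locus_bp, n_mut)) - 1L
  desc <- genealogy_descendants(gen)
  list(pos = pos, carriers = desc[branch, , drop = FALSE])
}

# Convert a genealogy to an ape phylo (tips keep their index order).
genealogy_to_phylo <- function(gen, tip_labels) {
  n <- gen$n
  n_nodes <- length(gen$time)
  ape_id <- function(v) ifelse(v <= n, v, 3L * n - v)  # root -> n + 1
  edge <- matrix(0L, n_nodes - 1L, 2L)
  elen <- numeric(n_nodes - 1L)
  row <- 0L
  for (v in (n + 1L):n_nodes) {
    for (ch in c(gen$child1[v], gen$child2[v])) {
      row <- row + 1L
      edge[row, ] <- c(ape_id(v), ape_id(ch))
      elen[row] <- gen$time[v] - gen$time[ch]
    }
  }
  structure(list(edge = edge, edge.length = elen, Nnode = n - 1L,
                 tip.label = tip_labels), class = "phylo")
}
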