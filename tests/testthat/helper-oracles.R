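# Handcrafted fixed-width PDB writer, independent of the package's own
# fixture writer, for identity read-back tests.
write_handmade_pdb <- function(path, atoms) {
  lines <- sprintf(
    "HETATM%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    sprintf(" %-3s", atoms$name),
    atoms$alt %||% rep("", nrow(atoms)),
    atoms$resname, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z,
    atoms$occ %||% rep(1, nrow(atoms)), 0,
    atoms$element %||% rep("C", nrow(atoms)))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hand_atoms <- function(name, x, y, z, resname = "CYC", chain = "X",
                       resno = 1L, occ = 1, alt = "", element = "C") {
  data.frame(name = name, x = x, y = y, z = z, resname = resname,
             chain = chain, resno = resno, occ = occ, alt = alt,
             element = element, stringsAsFactors = FALSE)
}

# O(n^2) brute-force pair scan, the reference for graph construction
brute_force_edges <- function(sites, cutoff) {
  n <- nrow(sites)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt((sites$x[i] - sites$x[j])^2 + (sites$y[i] - sites$y[j])^2 +
                  (sites$z[i] - sites$z[j])^2)
      if (d <= cutoff) {
        a <- sites$site_id[i]; b <- sites$site_id[j]
        out[[length(out) + 1L]] <- data.frame(
          site_a = min(a, b), site_b = max(a, b), distance = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(site_a = character(), site_b = character(),
                      distance = double()))
  }
  res <- do.call(rbind, out)
  res[order(res$site_a, res$site_b), ]
}

# exhaustive simple-path enumeration between two nodes; independent oracle
# for both shortest-path objectives
enumerate_paths <- function(edges, src, dst) {
  nodes <- unique(c(edges$site_a, edges$site_b, src, dst))
  adj <- lapply(setNames(nodes, nodes), function(v) {
    rbind(
      data.frame(to = edges$site_b[edges$site_a == v],
                 d = edges$distance[edges$site_a == v]),
      data.frame(to = edges$site_a[edges$site_b == v],
                 d = edges$distance[edges$site_b == v]))
  })
  results <- list()
  walk <- function(v, visited, total, maxstep) {
    if (v == dst) {
      results[[length(results) + 1L]] <<- c(total = total, maxstep = maxstep)
      return(invisible())
    }
    nb <- adj[[v]]
    for (k in seq_len(nrow(nb))) {
      w <- nb$to[k]
      if (!(w %in% visited)) {
        walk(w, c(visited, w), total + nb$d[k], max(maxstep, nb$d[k]))
      }
    }
  }
  walk(src, src, 0, 0)
  if (!length(results)) return(NULL)
  as.data.frame(do.call(rbind, results))
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3))) * sample(c(-1, 1), 1)
}

random_site_cloud <- function(n, box = 60) {
  tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n)),
    x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
    z = stats::runif(n, 0, box))
}
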