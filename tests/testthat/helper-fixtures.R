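# Shared fixtures and independent oracles, all built in code.

# tibble of interaction records from compact arguments
make_records <- function(date, plant, visitor, visits,
                         site = "A", fg = "bees") {
  d <- as.Date(date)
  tibble::tibble(
    date = d, site = site, plant = plant, visitor = visitor,
    functional_group = fg, visits = as.integer(visits),
    doy = as.integer(lubridate::yday(d))
  )
}

# bipnet from a plain matrix, auto-labelled
make_net <- function(m, label = "", date = as.Date(NA)) {
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  bipnet(m, label = label, date = date)
}

# random bipnet with no empty rows/columns
random_net <- function(np, nv, lambda = 1.5) {
  repeat {
    m <- matrix(stats::rpois(np * nv, lambda), np, nv)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  make_net(m)
}

# --- exhaustive-enumeration oracle for modularity -----------------------------

# all set partitions of n elements as restricted-growth strings
set_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  rec <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1]] <<- rgs[seq_len(n)]
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) {
      rgs[i] <<- v
      rec(i + 1, max(maxv, v))
    }
  }
  rec(1, 0)
  out
}

# brute-force maximum of Q over every partition of the species set
brute_force_q <- function(net) {
  labs <- c(rownames(net), colnames(net))
  best <- -Inf
  for (p in set_partitions(length(labs))) {
    q <- modularity_q(net, stats::setNames(p, labs))
    if (q > best) best <- q
  }
  best
}

# two-block fixture: 2 plants + 2 visitors per block, within-block weight 3
two_block_net <- function(w_in = 3, w_out = 0) {
  m <- matrix(w_out, 4, 4)
  m[1:2, 1:2] <- w_in
  m[3:4, 3:4] <- w_in
  make_net(m)
}

# temporary file with given lines
write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
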