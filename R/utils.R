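# Internal helpers shared across modules.

# scalar validators ---------------------------------------------------------

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min)
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  as.integer(x)
}

check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) abort(sprintf("`%s` must be a single number in %s.", name,
                         if (open) "(0, 1)" else "[0, 1]"))
  as.numeric(x)
}

# network-internal id handling ----------------------------------------------

node_ids <- function(network, nodes, arg = "nodes") {
  idx <- match(nodes, network$nodes)
  if (anyNA(idx))
    abort(sprintf("%s not in network: %s", arg,
                  paste(head(nodes[is.na(idx)], 5L), collapse = ", ")))
  idx
}

# attribute-preserving tibble subclass constructor
new_tbl_subclass <- function(x, class, ...) {
  out <- as_tibble(x)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}
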