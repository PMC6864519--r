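# Small fixtures shared across test files.

one_route <- function(values, id = "X1") {
  tibble::tibble(route_id = id, seq = seq_along(values), value = values)
}

# Band labels and groups matching the six-route contingency layout:
# X = {X3 Desirable, X1 & X2 Acceptable}, Y = {Y1 Desirable, Y2 Acceptable,
# Y3 Caution}.
six_route_labels <- function() {
  tibble::tibble(
    route_id = c("X1", "X2", "X3", "Y1", "Y2", "Y3"),
    band = c("Acceptable", "Acceptable", "Desirable",
             "Desirable", "Acceptable", "Caution")
  )
}

six_route_groups <- function() {
  tibble::tibble(route_id = c("X1", "X2", "X3", "Y1", "Y2", "Y3"),
                 group = c("X", "X", "X", "Y", "Y", "Y"))
}

# Brute-force oracle: exact one-sided rank-sum p-value by enumerating all
# assignments of pooled ranks to the y-sample (no ties assumed).
exact_ranksum_p <- function(y, x) {
  pooled <- c(y, x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(y)])
  combos <- utils::combn(length(pooled), length(y))
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(w_all >= w_obs)
}
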