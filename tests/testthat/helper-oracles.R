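# Brute-force oracles, written independently of the package implementations:
# plain double loops and direct formula evaluation on small instances.

brute_c_index <- function(times, events, risks) {
  conc <- 0; comp <- 0
  n <- length(times)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (events[i] == 1 && times[i] < times[j]) {
      comp <- comp + 1
      if (risks[i] > risks[j]) conc <- conc + 1
      else if (risks[i] == risks[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

brute_impact <- function(risks, status, pt) {
  pred <- risks >= pt
  c(TP = sum(pred == 1 & status == 1), FP = sum(pred == 1 & status == 0),
    FN = sum(pred == 0 & status == 1), TN = sum(pred == 0 & status == 0))
}

brute_dcal <- function(F_values, events, B) {
  mass <- numeric(B)
  for (i in seq_along(F_values)) {
    f <- F_values[i]
    if (events[i] == 1) {
      b <- if (f == 0) 1 else ceiling(f * B)
      mass[min(b, B)] <- mass[min(b, B)] + 1
    } else {
      for (b in 1:B) {
        lo <- (b - 1) / B; hi <- b / B
        mass[b] <- mass[b] + max(hi - max(lo, f), 0) / max(1 - f, 1e-12)
      }
    }
  }
  sum((mass / length(F_values) - 1 / B)^2)
}

brute_nb <- function(risks, status, pt) {
  n <- length(risks)
  tp <- sum(risks >= pt & status == 1)
  fp <- sum(risks >= pt & status == 0)
  tp / n - fp / n * pt / (1 - pt)
}
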