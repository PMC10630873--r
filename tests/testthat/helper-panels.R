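# shared fixtures, all built in code

phi <- (1 + sqrt(5)) / 2

reg <- defaultRegistry()
liver_ind <- rownames(reg)[reg$is_liver_panel]

# a panel where every liver indicator falls strongly (ratio > phi^1.69)
# toward its reference interval and everything else is unchanged
strong_responder_panel <- function() {
  hi <- ifelse(is.na(reg$ref_high), reg$ref_low * 2, reg$ref_high)
  pre <- post <- stats::setNames((reg$ref_low + hi) / 2, rownames(reg))
  pre[is.na(pre)] <- hi[is.na(pre)] / 2       # high-bound-only indicators
  post <- pre
  pre[liver_ind] <- hi[match(liver_ind, rownames(reg))] * 10
  post[liver_ind] <- hi[match(liver_ind, rownames(reg))] * 1.5
  list(pre = pre, post = post)
}
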