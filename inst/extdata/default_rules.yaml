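# Method-resolution rule table.
#
# Rules apply top to bottom. A rule fires when every condition in `when`
# holds against the review's reported methods: a value matches
# case-insensitively, and the special value `missing` matches an
# unreported field. A firing rule fills the fields in `set` -- but never a
# field the review itself reported. The last rule must have no `when`
# conditions (the universal fallback), which makes resolution total.
#
# This file mirrors the table built into the package
# (default_rule_table()); copy and edit it, then pass the copy via
# read_rule_table() or `--rules`, to encode different software defaults.
rules:
  - id: mh_implies_fixed
    when: {pooling: mantel_haenszel}
    set: {model: fixed, tau2_estimator: none}
  - id: fixed_implies_no_tau2
    when: {model: fixed}
    set: {tau2_estimator: none}
  - id: revman_defaults
    when: {software: revman}
    set: {tau2_estimator: DL, ci_method: wald_z}
  - id: stata_metan_defaults
    when: {package_or_command: metan}
    set: {tau2_estimator: DL, ci_method: wald_z}
  - id: r_meta_defaults
    when: {software: r}
    set: {tau2_estimator: REML}
  - id: fallback
    set:
      model: random
      pooling: inverse_variance
      tau2_estimator: REML
      ci_method: wald_z
      continuity: add_half
      level: 0.95
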