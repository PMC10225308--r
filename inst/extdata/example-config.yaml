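# Annotated run configuration for dopacca::read_run_config().
# Every field is optional; omitted fields take the package defaults shown here.

seed: 1                    # master seed; spawns per-stage seeds deterministically
mode: age_as_variable      # or age_residualized (age dropped and partialled out)
out_dir: null              # directory for CSV artifacts; null = return only
verbose: false

task:
  n_blocks: 10             # blocks per session
  trials_per_block: 6
  gain_stock_payoffs: [2, 10]    # [low, high] stock dividends, gain frame
  loss_stock_payoffs: [-10, -2]  # "high" is the better (less negative) outcome
  gain_bond: 6
  loss_bond: -6
  q_high: 0.7              # P(high dividend | good stock); bad stock: 1 - q_high
  prior_good: 0.5          # prior that a block's stock is good
  n_gain_blocks: 5         # remaining blocks are loss-framed

cohort:
  n_participants: 35
  age_range: [26, 79]      # years, uniform
  inter_region_corr: 0.4   # common residual correlation of log binding potentials
  regions:                 # target natural-scale mean/SD of BP_ND and the
    - {region: midbrain,            mean: 1.73, sd: 0.41, age_slope: -0.45}
    - {region: amygdala,            mean: 3.08, sd: 0.80, age_slope: -0.15}
    - {region: insula,              mean: 1.86, sd: 0.55, age_slope: -0.40}
    - {region: anterior_cingulate,  mean: 1.19, sd: 0.38, age_slope: -0.40}
  param_base:              # baseline agent parameters
    stickiness: 1.0
    risk_propensity: 0.85
    inv_temperature: 1.0
    belief_slope: 1.0
    belief_bias: 0.0
    report_noise: 15
  param_noise_sd:          # residual SD of each parameter across participants
    stickiness: 0.30
    risk_propensity: 0.30
    inv_temperature: 0.20
    belief_slope: 0.15
    belief_bias: 0.30
    report_noise: 4
  linkage:                 # standardized weights from (age, regions) to params;
                           # unlisted entries are zero
    - {param: stickiness,  variable: age,      weight: 0.30}
    - {param: stickiness,  variable: amygdala, weight: -0.35}
    - {param: belief_bias, variable: amygdala, weight: 0.30}
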