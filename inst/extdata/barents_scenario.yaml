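# Bundled synthetic Barents-like scenario: a red-noise upstream index (AMO
# analogue), two downstream hydrographic sections lagging it by 3 and 4
# years, a stock responding to hydrography 7 years after the upstream index
# with a weak negative harvest-rate effect leading by 2 years, and a
# recruitment series leading the stock by 2 years.
mode: synthetic
scenario:
  n_years: 60
  start_year: 1958
predictand: TSB
predictors: [FSC, BSO, AMO]
screen_predictors: [AMO, FSC, BSO]
lead: 7
lag_min: 0
lag_max: 10
detrend_screening: true
anomalize: true
n_iter: 500
fit_frac: 0.8
n_surrogates: 500
alpha: 0.05
persistence_lags: [1, 2, 3, 4, 5, 6, 7]
attribution_lags: [0, 1, 2, 3, 4, 5]
highpass_cutoff: 5
seed: 1
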