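# Base-case model inputs: monthly transition probabilities, utilities,
# costs, discounting, horizon and willingness to pay, plus per-strategy
# procedure cost, severe (Clavien-Dindo III+) complication probability
# and mean length of stay.
#
# met_mortality: the metastatic survival curve is an exponential
# anchored on ~10% 5-year overall survival under targeted systemic
# therapy in metastatic RCC: p_month = 1 - 0.10^(1/60) = 0.03765.
#
# c_bed_night: per-night hospital bed tariff.  Derived by reconciling
# the base-case incremental cost of -8725 EUR against the structural
# increment from procedure and complication costs alone (-7736.04 EUR):
# the residual -988.96 EUR over the 0.77-night length-of-stay difference
# gives 1284.4 EUR/night, under which both arms imply the same
# metastatic-state cost.  See the methods vignette.
shared:
  p_local_recurrence: 0.0018      # per month
  p_metastasis: 0.0035            # per month
  p_background_death: 0.0012      # per month
  met_mortality:
    family: exponential
    p_month: 0.03765
  u_stable: 0.76                  # per year
  u_local_recurrence: 0.70
  u_metastatic: 0.66
  q_intervention_month: 0.058     # QALY accrued in the procedure month
  du_complication: 0.05           # one-time QALY decrement per complication
  c_complication: 4332.0          # EUR, one-time
  c_advanced_monthly: 2500.0      # EUR per month in the metastatic state
  c_bed_night: 1284.4             # EUR per hospital night (derived; see above)
  discount_annual: 0.03
  horizon_cycles: 60
  wtp: 40000.0                    # EUR per QALY
strategies:
  - name: PCA
    c_procedure: 7427.0
    p_complication: 0.055
    mean_los: 1.13                # nights (85/91 day cases + 6 at 3.0)
  - name: RAPN
    c_procedure: 15293.0
    p_complication: 0.025
    mean_los: 1.90
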