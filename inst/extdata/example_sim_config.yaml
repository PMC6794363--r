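# Example simulation configuration: any subset of sim_config()'s arguments.
# Load with read_sim_config().
n_participants: 120
seed: 42
rho_ue_ee: 0.70
rt_base_ms: 1300
rt_cap_ms: 4000
trait_means: {cr: 42, ue: 36, ee: 36}
trait_sds: {cr: 22, ue: 19, ee: 28}
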