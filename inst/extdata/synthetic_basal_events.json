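{"subject_id":"SYN01","segment":"basal","qrs_onset_ms":40,"pv_open_ms":110,"pv_close_ms":390,"framerate_hz":75}
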