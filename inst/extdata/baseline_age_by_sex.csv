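age_group,female,male
young,33,23
middle_aged,43,27
older,25,22
retirement,31,28
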