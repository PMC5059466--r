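# prune_epsilon: 0.01
guild	mass	herbivore_only
plant	     1	FALSE
plant	    50	FALSE
plant	  2500	FALSE
animal	   100	FALSE
animal	  5000	FALSE
animal	250000	FALSE
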