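butyrate_producers	Butyrate producing gut bacteria	853	301301	166486	39491	649756	33043	831
propionate_producers	Propionate producing gut bacteria	165179	817	820	239935	218538	29466
acetate_producers	Acetate producing gut bacteria	216816	1680	40520	28117	33038
proteobacteria_bloom	Taxa expanding in dysbiosis	562	573	1351	1304	29466
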