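wavelength_nm	epsilon
450	0.856621
451	0.826923
452	0.798268
453	0.770618
454	0.74394
455	0.718199
456	0.693361
457	0.669396
458	0.646273
459	0.623962
460	0.602435
461	0.581664
462	0.561624
463	0.542289
464	0.523633
465	0.505634
466	0.488269
467	0.471515
468	0.455351
469	0.439757
470	0.424712
471	0.410198
472	0.396197
473	0.38269
474	0.369661
475	0.357093
476	0.344971
477	0.333278
478	0.322001
479	0.311126
480	0.300638
481	0.290525
482	0.280775
483	0.271375
484	0.262314
485	0.253582
486	0.245168
487	0.237063
488	0.229258
489	0.221744
490	0.214515
491	0.207562
492	0.20088
493	0.194465
494	0.188311
495	0.182416
496	0.176778
497	0.171396
498	0.166271
499	0.161405
500	0.156803
501	0.152471
502	0.148416
503	0.144649
504	0.141183
505	0.138032
506	0.135217
507	0.132756
508	0.130674
509	0.128999
510	0.12776
511	0.126991
512	0.126729
513	0.127011
514	0.127882
515	0.129385
516	0.131566
517	0.134474
518	0.138157
519	0.142664
520	0.148043
521	0.154341
522	0.161601
523	0.169864
524	0.179164
525	0.189529
526	0.20098
527	0.213529
528	0.227178
529	0.241914
530	0.257717
531	0.274549
532	0.292358
533	0.311078
534	0.330628
535	0.350908
536	0.371805
537	0.393192
538	0.414924
539	0.436846
540	0.458789
541	0.480577
542	0.502024
543	0.52294
544	0.543131
545	0.562405
546	0.580573
547	0.597449
548	0.612861
549	0.626646
550	0.638656
551	0.648762
552	0.656853
553	0.662842
554	0.666664
555	0.668277
556	0.667668
557	0.664847
558	0.659849
559	0.652736
560	0.64359
561	0.632517
562	0.619643
563	0.605111
564	0.589078
565	0.571714
566	0.553199
567	0.533717
568	0.513458
569	0.49261
570	0.471358
571	0.449885
572	0.428363
573	0.406955
574	0.385813
575	0.365077
576	0.344869
577	0.325301
578	0.306465
579	0.28844
580	0.271287
581	0.255055
582	0.239775
583	0.225467
584	0.212137
585	0.199779
586	0.188377
587	0.177908
588	0.168338
589	0.15963
590	0.151738
591	0.144615
592	0.138211
593	0.132474
594	0.127351
595	0.122788
596	0.118735
597	0.11514
598	0.111955
599	0.109134
600	0.106633
601	0.104412
602	0.102433
603	0.100662
604	0.0990675
605	0.0976206
606	0.0962961
607	0.0950712
608	0.0939259
609	0.0928427
610	0.0918062
611	0.0908033
612	0.0898228
613	0.0888551
614	0.0878922
615	0.0869277
616	0.0859563
617	0.0849735
618	0.0839763
619	0.082962
620	0.081929
621	0.0808761
622	0.0798026
623	0.0787084
624	0.0775936
625	0.0764588
626	0.0753048
627	0.0741324
628	0.0729428
629	0.0717374
630	0.0705175
631	0.0692846
632	0.0680403
633	0.0667861
634	0.0655237
635	0.0642548
636	0.0629809
637	0.0617037
638	0.0604248
639	0.0591459
640	0.0578686
641	0.0565943
642	0.0553246
643	0.054061
644	0.0528049
645	0.0515576
646	0.0503204
647	0.0490948
648	0.0478817
649	0.0466825
650	0.0454981
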