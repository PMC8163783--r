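# SWC written by neuriteflow
1 1 0 0 0 1 -1
2 3 0.154459652 0.0966259551 0.932531494 1 1
3 3 0.320212296 0.200467554 1.86234455 1 2
4 3 0.497213931 0.311497109 2.78924919 1 3
5 3 0.685416015 0.42968403 3.71305717 1 4
6 3 0.884765529 0.554994865 4.63358218 1 5
7 3 1.09520505 0.687393343 5.55064009 1 6
8 3 1.31667281 0.826840426 6.46404902 1 7
9 3 1.54910284 0.973294363 7.37362963 1 8
10 3 1.79242496 1.12671074 8.27920519 1 9
11 3 2.04656499 1.28704256 9.18060183 1 10
12 3 2.31144477 1.45424029 10.0776486 1 11
13 3 2.58698229 1.62825193 10.9701778 1 12
14 3 2.87309182 1.8090231 11.8580249 1 13
15 3 3.16968403 1.9964971 12.7410288 1 14
16 3 3.47666608 2.190615 13.619032 1 15
17 3 3.79394179 2.39131573 14.4918806 1 16
18 3 4.12141172 2.59853611 15.3594246 1 17
19 3 3.83640679 2.77356587 16.2818047 0.85 18
20 3 3.5786031 2.9274128 17.2158907 0.85 19
21 3 3.34861949 3.05966054 18.1604892 0.85 20
22 3 3.14700842 3.16994592 19.1143437 0.85 21
23 3 2.97425038 3.25796298 20.076142 0.85 22
24 3 2.83074876 3.32346638 21.0445246 0.85 23
25 3 2.71682566 3.36627427 22.0180939 0.85 24
26 3 2.63271846 3.3862704 22.9954242 0.85 25
27 3 2.57857739 3.38340549 23.9750715 0.85 26
28 3 2.55446409 3.35769789 24.9555846 0.85 27
29 3 2.56035123 3.30923334 25.9355156 0.85 28
30 3 2.59612317 3.23816406 26.9134306 0.85 29
31 3 2.66157763 3.14470692 27.8879201 0.85 30
32 3 2.75642841 3.02914104 28.8576088 0.85 31
33 3 2.88030893 2.89180457 29.821165 0.85 32
34 3 3.0327767 2.73309101 30.7773093 0.85 33
35 3 4.74313884 2.92112869 16.0429296 0.85 18
36 3 5.35114668 3.24506522 16.738042 0.85 35
37 3 5.9449385 3.57026026 17.4447591 0.85 36
38 3 6.52400863 3.89662104 18.16306 0.85 37
39 3 7.08784328 4.2240472 18.892904 0.85 38
40 3 7.63592145 4.55243064 19.63423 0.85 39
41 3 8.16771587 4.88165534 20.3869554 0.85 40
42 3 8.6826942 5.2115972 21.1509746 0.85 41
43 3 9.18032018 5.54212396 21.9261585 0.85 42
44 3 9.66005503 5.87309509 22.7123533 0.85 43
45 3 10.1213588 6.20436175 23.5093796 0.85 44
46 3 10.5636922 6.53576682 24.3170315 0.85 45
47 3 10.9865177 6.86714492 25.135076 0.85 46
48 3 11.389302 7.19832249 25.9632522 0.85 47
49 3 11.7715175 7.52911797 26.8012709 0.85 48
50 3 12.1326442 7.85934196 27.648814 0.85 49
51 3 12.4721719 8.18879749 28.5055343 0.85 50
52 3 12.7896024 8.51728033 29.3710553 0.85 51
53 3 13.0844515 8.84457939 30.2449712 0.85 52
54 3 13.3562511 9.17047708 31.1268472 0.85 53
55 3 3.65713906 2.83653768 31.4778153 0.7225 34
56 3 4.29201165 2.95751091 32.1659581 0.7225 55
57 3 4.93701847 3.0959867 32.8412572 0.7225 56
58 3 5.59176719 3.25191802 33.5032449 0.7225 57
59 3 6.25585027 3.42523477 34.151468 0.7225 58
60 3 6.92884624 3.61584388 34.7854892 0.7225 59
61 3 7.610321 3.82362953 35.4048885 0.7225 60
62 3 8.29982918 4.04845345 36.0092649 0.7225 61
63 3 8.99691562 4.29015543 36.5982376 0.7225 62
64 3 9.70111686 4.54855381 37.1714471 0.7225 63
65 3 10.4119627 4.82344623 37.7285562 0.7225 64
66 3 11.1289777 5.11461033 38.2692513 0.7225 65
67 3 11.8516828 5.4218047 38.7932429 0.7225 66
68 3 12.579597 5.74476976 39.3002663 0.7225 67
69 3 13.3122385 6.08322886 39.7900826 0.7225 68
70 3 14.049127 6.43688938 40.2624786 0.7225 69
71 3 2.65012795 2.45060337 31.6202705 0.7225 34
72 3 2.2476337 2.17487691 32.4561988 0.7225 71
73 3 1.82619393 1.90580925 33.2849292 0.7225 72
74 3 1.38668097 1.64328568 34.1063381 0.7225 73
75 3 0.929938248 1.38718102 34.9203402 0.7225 74
76 3 0.456779302 1.13736124 35.7268845 0.7225 75
77 3 -0.0320127694 0.893685054 36.5259509 0.7225 76
78 3 -0.535685589 0.65600531 37.3175473 0.7225 77
79 3 -1.05351752 0.424170277 38.1017064 0.7225 78
80 3 -1.58481745 0.198024805 38.8784828 0.7225 79
81 3 -2.12892442 -0.0225886408 39.6479503 0.7225 80
82 3 -2.68520706 -0.237829051 40.4101997 0.7225 81
83 3 -3.25306294 -0.447856047 41.1653363 0.7225 82
84 3 -3.83191775 -0.65282916 41.913478 0.7225 83
85 3 -4.42122454 -0.852907191 42.6547534 0.7225 84
86 3 -5.02046273 -1.04824766 43.3892999 0.7225 85
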